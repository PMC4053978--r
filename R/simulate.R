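#' Configuration for a synthetic colony-array screen
#'
#' Describes the generative model behind a synthetic screen: per-colony
#' expected growth rate is a product of a wild-type base rate, a carbon
#' multiplier, a nitrogen multiplier, a carbon-by-nitrogen interaction
#' multiplier, a strain fitness multiplier and (for planted hits only) a
#' gene-environment effect multiplier. A smooth low-order polynomial bias
#' surface is added per plate on the rate scale, colony areas grow linearly
#' from the pin size and are observed with multiplicative log-normal noise,
#' and some colonies go missing entirely.
#'
#' Defaults emulate the genome-wide design: 16 plates of 16 x 24 positions,
#' 701 wild-type positions, 4,772 mutants, 28 carbon-by-nitrogen conditions
#' with the glucose:ammonium reference screened as six replicate plate sets,
#' plates scanned at 0/5/10/24 hours (plus 48 h for glycerol).
#'
#' @param base_rate Wild-type glucose:ammonium growth rate, pixels/second.
#' @param a0 Initial (pin) colony area in pixels.
#' @param carbon_mult,nitrogen_mult Named positive multipliers, one per
#'   source; the reference sources (glucose, ammonium) are 1.
#' @param interaction_mult Named positive multipliers for `"carbon:nitrogen"`
#'   pairs; unlisted pairs default to 1 (independent contributions). The
#'   default leaves exactly three non-reference cells at 1.
#' @param fitness_sdlog Log-scale SD of the fitness multipliers of
#'   quasi-neutral mutants (drawn log-normal with median 1).
#' @param deleterious_frac Fraction of mutants with a frank fitness defect;
#'   their multipliers are drawn log-uniform on
#'   `deleterious_range`. Deletion collections show exactly this shape: a
#'   quasi-neutral majority plus a broad slow tail, and the slow tail is
#'   what anchors the low-rate end of the LOWESS ratio fit.
#' @param deleterious_range Fitness range of the deleterious class.
#' @param n_slow,n_fast Number of planted slow/fast gene-environment effects.
#' @param slow_effect,fast_effect Multipliers for planted effects (<1 slow,
#'   >1 fast).
#' @param planted Optional explicit tibble of planted effects with columns
#'   `strain`, `condition` (a `"carbon:nitrogen"` pair label), `effect`;
#'   overrides `n_slow`/`n_fast`.
#' @param spatial_frac Amplitude of the additive spatial bias surface as a
#'   fraction of the condition's expected wild-type rate (0 disables).
#' @param noise_sd Log-scale SD of the multiplicative observation noise on
#'   areas (0 disables).
#' @param missing_prob Probability that a colony yields no usable series.
#' @param n_plates,n_rows,n_cols,n_mutants,n_wildtype Array design, see
#'   [design_layout()].
#' @param ga_replicates Number of glucose:ammonium replicate plate sets.
#' @param conditions Optional character vector of `"carbon:nitrogen"` pair
#'   labels to restrict the grid (default: all 28).
#' @param scan_hours Scan times in hours; `glycerol_extra_hour` is appended
#'   for glycerol conditions.
#' @return A list of class `cn_truth` holding the configuration.
#' @export
synthetic_truth <- function(base_rate = 0.02,
                            a0 = 50,
                            carbon_mult = c(glucose = 1, galactose = 0.9,
                                            ribose = 0.35, glycerol = 0.15),
                            nitrogen_mult = c(ammonium = 1, glutamine = 0.97,
                                              glutamate = 0.85, arginine = 0.75,
                                              proline = 0.7, allantoin = 0.65,
                                              urea = 0.55),
                            interaction_mult = c("ribose:glutamate" = 1.4,
                                                 "glycerol:glutamate" = 1.35,
                                                 "ribose:glutamine" = 1.15,
                                                 "galactose:proline" = 1.12,
                                                 "ribose:proline" = 1.2,
                                                 "glycerol:proline" = 1.25,
                                                 "galactose:glutamate" = 1.1,
                                                 "glycerol:glutamine" = 1.1,
                                                 "ribose:urea" = 0.85,
                                                 "galactose:arginine" = 0.9,
                                                 "ribose:arginine" = 0.8,
                                                 "glycerol:urea" = 0.85,
                                                 "glycerol:arginine" = 0.88,
                                                 "galactose:glutamine" = 1.08,
                                                 "glycerol:allantoin" = 0.9),
                            fitness_sdlog = 0.03,
                            deleterious_frac = 0.25,
                            deleterious_range = c(0.3, 0.95),
                            n_slow = 200L, n_fast = 40L,
                            slow_effect = 0.5, fast_effect = 1.5,
                            planted = NULL,
                            spatial_frac = 0.05,
                            noise_sd = 0.05,
                            missing_prob = 0.02,
                            n_plates = 16L, n_rows = 16L, n_cols = 24L,
                            n_mutants = 4772L, n_wildtype = 701L,
                            ga_replicates = 6L,
                            conditions = NULL,
                            scan_hours = c(0, 5, 10, 24),
                            glycerol_extra_hour = 48) {
  stopifnot(base_rate > 0, a0 >= 0, all(carbon_mult > 0),
            all(nitrogen_mult > 0), all(interaction_mult > 0),
            noise_sd >= 0, missing_prob >= 0, missing_prob < 1,
            spatial_frac >= 0, fitness_sdlog >= 0,
            deleterious_frac >= 0, deleterious_frac < 1,
            length(deleterious_range) == 2, all(deleterious_range > 0))
  stopifnot(all(names(carbon_mult) %in% carbon_sources()),
            all(names(nitrogen_mult) %in% nitrogen_sources()))
  if (!is.null(planted)) {
    stopifnot(all(c("strain", "condition", "effect") %in% names(planted)),
              all(planted$effect > 0))
  }
  structure(as.list(environment()), class = "cn_truth")
}

#' Simulate a complete synthetic screening experiment
#'
#' Realizes a [synthetic_truth()] configuration into colony-area time
#' courses over the full plate array and condition grid, with known ground
#' truth (strain fitness draws, planted gene-environment effects, spatial
#' bias surfaces). The same configuration and seed always produce the same
#' experiment.
#'
#' @param config A `cn_truth` configuration from [synthetic_truth()].
#' @param seed Integer seed controlling every random draw.
#' @return A list of class `cn_experiment` with elements `colonies` (the
#'   colony table, see [read_colony_table()]), `layout` (the plate layout),
#'   `strain_fitness` (realized per-strain multipliers), `planted` (the
#'   planted gene-environment effects) and `config`.
#' @export
simulate_experiment <- function(config = synthetic_truth(), seed = 1L) {
  stopifnot(inherits(config, "cn_truth"))
  with_preserved_seed({
    set.seed(as.integer(seed))
    layout <- design_layout(config$n_plates, config$n_rows, config$n_cols,
                            config$n_mutants, config$n_wildtype)
    if (!"WT" %in% layout$strain) {
      stop("layout lacks the wild-type strain", call. = FALSE)
    }
    mutants <- setdiff(unique(layout$strain), "WT")
    n_mut <- length(mutants)
    slowcl <- stats::runif(n_mut) < config$deleterious_frac
    fit_mult <- exp(stats::rnorm(n_mut, 0, config$fitness_sdlog))
    lo <- log(config$deleterious_range)
    fit_mult[slowcl] <- exp(stats::runif(sum(slowcl), lo[1], lo[2]))
    strain_fitness <- tibble::tibble(strain = c("WT", mutants),
                                     fitness = c(1, fit_mult))

    grid <- condition_grid(config$ga_replicates)
    if (!is.null(config$conditions)) {
      grid <- grid[paste0(grid$carbon, ":", grid$nitrogen) %in%
                     config$conditions, , drop = FALSE]
      if (nrow(grid) == 0) stop("no conditions left after restriction",
                                call. = FALSE)
    }

    planted <- realize_planted(config, mutants, grid)

    cond_tabs <- purrr::pmap(grid, function(carbon, nitrogen, replicate,
                                            condition) {
      simulate_condition(config, layout, strain_fitness, planted,
                         carbon, nitrogen, replicate, condition)
    })
    colonies <- dplyr::bind_rows(cond_tabs)
    structure(list(colonies = colonies, layout = layout,
                   strain_fitness = strain_fitness, planted = planted,
                   config = config, seed = as.integer(seed)),
              class = "cn_experiment")
  })
}

# choose planted (strain, pair) effects outside glucose:ammonium and glycerol
realize_planted <- function(config, mutants, grid) {
  if (!is.null(config$planted)) {
    return(tibble::as_tibble(config$planted))
  }
  pairs <- unique(paste0(grid$carbon, ":", grid$nitrogen))
  eligible <- setdiff(pairs[!startsWith(pairs, "glycerol")],
                      "glucose:ammonium")
  n <- config$n_slow + config$n_fast
  if (n == 0 || length(eligible) == 0 || length(mutants) == 0) {
    return(tibble::tibble(strain = character(), condition = character(),
                          effect = numeric()))
  }
  cells <- tidyr::expand_grid(strain = mutants, condition = eligible)
  take <- sample(nrow(cells), min(n, nrow(cells)))
  out <- cells[take, ]
  out$effect <- rep(c(config$slow_effect, config$fast_effect),
                    c(config$n_slow, config$n_fast))[seq_len(nrow(out))]
  out
}

simulate_condition <- function(config, layout, strain_fitness, planted,
                               carbon, nitrogen, replicate, condition) {
  pair <- paste0(carbon, ":", nitrogen)
  imult <- config$interaction_mult[pair]
  imult <- if (is.na(imult)) 1 else unname(imult)
  wt_rate <- config$base_rate * config$carbon_mult[[carbon]] *
    config$nitrogen_mult[[nitrogen]] * imult

  df <- dplyr::left_join(layout, strain_fitness, by = "strain")
  df$rate <- wt_rate * df$fitness
  pl <- planted[planted$condition == pair, ]
  if (nrow(pl) > 0) {
    idx <- match(df$strain, pl$strain)
    hit <- !is.na(idx)
    df$rate[hit] <- df$rate[hit] * pl$effect[idx[hit]]
  }

  if (config$spatial_frac > 0) {
    amp <- config$spatial_frac * wt_rate
    for (p in unique(df$plate)) {
      sel <- df$plate == p
      x <- 2 * (df$col[sel] - 1) / (config$n_cols - 1) - 1
      y <- 2 * (df$row[sel] - 1) / (config$n_rows - 1) - 1
      co <- stats::rnorm(5)
      surf <- co[1] * x + co[2] * y + co[3] * x * y +
        co[4] * (x^2 - 1 / 3) + co[5] * (y^2 - 1 / 3)
      df$rate[sel] <- pmax(df$rate[sel] + amp * surf / 2, 0)
    }
  }

  hours <- config$scan_hours
  if (carbon == "glycerol") hours <- c(hours, config$glycerol_extra_hour)
  times <- hours * 3600

  keep <- stats::runif(nrow(df)) >= config$missing_prob
  df <- df[keep, , drop = FALSE]
  n <- nrow(df)
  obs <- tidyr::expand_grid(df[, c("plate", "row", "col", "strain", "rate")],
                            time_s = times)
  obs$area_px <- config$a0 + obs$rate * obs$time_s
  if (config$noise_sd > 0) {
    obs$area_px <- obs$area_px * exp(stats::rnorm(nrow(obs), 0,
                                                  config$noise_sd))
  }
  tibble::tibble(
    plate = obs$plate, row = obs$row, col = obs$col, strain = obs$strain,
    carbon = carbon, nitrogen = nitrogen, replicate = replicate,
    time_s = obs$time_s, area_px = obs$area_px, curated_zero = FALSE,
    condition = condition
  )
}

#' Planted ground-truth effects of a synthetic experiment
#'
#' @param experiment A `cn_experiment` from [simulate_experiment()].
#' @return A tibble of planted gene-environment effects with columns
#'   `strain`, `condition` (pair label), `effect` and `direction`
#'   (`"slow"` if the multiplier is below 1, else `"fast"`).
#' @export
truth_table <- function(experiment) {
  stopifnot(inherits(experiment, "cn_experiment"))
  pl <- experiment$planted
  pl$direction <- ifelse(pl$effect < 1, "slow", "fast")
  dplyr::arrange(pl, .data$condition, .data$strain)
}

# evaluate an expression without disturbing the caller's RNG stream
with_preserved_seed <- function(expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
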