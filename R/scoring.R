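#' Modified z-scores for every position and condition
#'
#' For each array position on each experimental plate the residual between
#' the normalized rate and the glucose:ammonium reference rate is divided by
#' the combined variability
#' `sqrt(strain_sd^2 + plate_sd^2)`, where `strain_sd` is the positionwise SD
#' across the six reference replicates (see [build_reference()]) and
#' `plate_sd` is the SD of the residuals across the finite positions of that
#' plate, computed separately per condition --- it accounts for the general
#' growth variation on the plate. Negative z means the strain grew slower in
#' the condition than expected from the nutrient environment alone.
#'
#' @param normalized Tibble from [normalize_rates()] (optionally after
#'   [smooth_rates()]).
#' @param reference Tibble from [build_reference()].
#' @return A position-level tibble with columns `condition`, `plate`, `row`,
#'   `col`, `strain`, `is_wildtype`, `residual`, `plate_sd`, `z`. A cell is
#'   missing iff its normalized or reference rate is missing.
#' @export
compute_zscores <- function(normalized, reference) {
  ref <- reference[, c("plate", "row", "col", "ga_ref", "strain_sd")]
  d <- dplyr::inner_join(normalized, ref, by = c("plate", "row", "col"))
  d$residual <- d$norm_rate - d$ga_ref
  d <- d |>
    dplyr::group_by(.data$condition, .data$plate) |>
    dplyr::mutate(plate_sd = stats::sd(.data$residual, na.rm = TRUE)) |>
    dplyr::ungroup()
  denom <- sqrt(d$strain_sd^2 + d$plate_sd^2)
  bad <- is.finite(d$residual) & (!is.finite(denom) | denom == 0)
  if (any(bad)) {
    ex <- d[bad, c("condition", "plate", "row", "col")]
    stop("zero combined variance; z undefined at ", sum(bad),
         " position(s), e.g. ", ex$condition[1], " plate ", ex$plate[1],
         " row ", ex$row[1], " col ", ex$col[1], call. = FALSE)
  }
  d$z <- d$residual / denom
  dplyr::select(d, "condition", "plate", "row", "col", "strain",
                "is_wildtype", "residual", "plate_sd", "z")
}

#' Collapse position-level z-scores to gene level
#'
#' Strains placed at several array positions are averaged at the z level,
#' giving one z per (strain, condition instance).
#'
#' @param zscores Position-level tibble from [compute_zscores()].
#' @param include_wildtype Keep the wild-type strain as a row (default
#'   `FALSE`; the wild-type feeds the null model instead).
#' @return Tibble with columns `strain`, `condition`, `z`.
#' @export
gene_zscores <- function(zscores, include_wildtype = FALSE) {
  d <- if (include_wildtype) zscores else zscores[!zscores$is_wildtype, ]
  d |>
    dplyr::group_by(.data$strain, .data$condition) |>
    dplyr::summarise(z = if (all(is.na(.data$z))) NA_real_ else
      mean(.data$z, na.rm = TRUE), .groups = "drop")
}

#' Wild-type null distribution per condition
#'
#' The wild-type replicates scattered across the array (701 in the
#' genome-wide design) provide, for each condition, an empirical null for
#' the z-scores. Its moments define the normal distribution from which
#' mutant p-values are computed.
#'
#' @param zscores Position-level tibble from [compute_zscores()].
#' @param min_n Minimum finite wild-type z values required per condition.
#' @return Tibble with columns `condition`, `mean`, `sd`, `n`.
#' @export
fit_null <- function(zscores, min_n = 100L) {
  wt <- zscores[zscores$is_wildtype & is.finite(zscores$z), ]
  null <- wt |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean = mean(.data$z), sd = stats::sd(.data$z),
                     n = dplyr::n(), .groups = "drop")
  low <- null$n < min_n
  if (any(low)) {
    stop("insufficient wild-type null (<", min_n, " values) in: ",
         paste(null$condition[low], collapse = ", "), call. = FALSE)
  }
  if (any(null$sd <= 0 | !is.finite(null$sd))) {
    stop("wild-type null SD must be positive in every condition",
         call. = FALSE)
  }
  null
}

#' Benjamini-Hochberg step-up rejection
#'
#' The classical step-up rule: sort the m p-values increasingly, find the
#' largest k with `p_(k) <= k/m * alpha`, and reject all tests with
#' `p <= p_(k)`.
#'
#' @param p Numeric vector of p-values (NAs allowed; never rejected).
#' @param alpha Target false discovery rate.
#' @return Logical vector, `TRUE` where rejected.
#' @export
bh_reject <- function(p, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  out <- rep(FALSE, length(p))
  ok <- which(is.finite(p))
  if (length(ok) == 0) return(out)
  ps <- sort(p[ok])
  m <- length(ps)
  below <- which(ps <= seq_len(m) / m * alpha)
  if (length(below) == 0) return(out)
  crit <- ps[max(below)]
  out[ok] <- p[ok] <= crit
  out
}

#' Condition-specific z-score thresholds at a target FDR
#'
#' One-sided p-values against the wild-type null (lower tail for slow
#' growth, upper tail for fast) are subjected to the Benjamini-Hochberg
#' procedure separately within each (condition, direction) family; the
#' threshold is the least extreme z among the rejected tests (an infinite
#' sentinel when nothing is rejected).
#'
#' @param gene_z Gene-level tibble from [gene_zscores()].
#' @param null Null tibble from [fit_null()].
#' @param fdr Target FDR level(s), default `c(0.10, 0.20)`.
#' @return Tibble with columns `condition`, `direction`, `fdr_level`,
#'   `z_threshold`, `n_rejected`. Slow thresholds are `<= 0 <=` fast
#'   thresholds, and thresholds at a stricter FDR are at least as extreme.
#' @export
bh_thresholds <- function(gene_z, null, fdr = c(0.10, 0.20)) {
  stopifnot(all(fdr > 0), all(fdr < 1))
  missing_null <- setdiff(unique(gene_z$condition), null$condition)
  if (length(missing_null) > 0) {
    stop("no null model for condition(s): ",
         paste(missing_null, collapse = ", "), call. = FALSE)
  }
  combos <- tidyr::expand_grid(condition = unique(gene_z$condition),
                               direction = c("fast", "slow"),
                               fdr_level = fdr)
  purrr::pmap(combos, function(condition, direction, fdr_level) {
    z <- gene_z$z[gene_z$condition == condition]
    nu <- null[null$condition == condition, ]
    p <- if (direction == "slow") {
      stats::pnorm(z, nu$mean, nu$sd)
    } else {
      stats::pnorm(z, nu$mean, nu$sd, lower.tail = FALSE)
    }
    rej <- bh_reject(p, fdr_level)
    thr <- if (!any(rej)) {
      if (direction == "slow") -Inf else Inf
    } else if (direction == "slow") {
      max(z[rej])
    } else {
      min(z[rej])
    }
    tibble::tibble(condition = condition, direction = direction,
                   fdr_level = fdr_level, z_threshold = thr,
                   n_rejected = sum(rej))
  }) |>
    dplyr::bind_rows()
}

#' Call fast and slow hits from z-scores and thresholds
#'
#' @param gene_z Gene-level tibble from [gene_zscores()].
#' @param thresholds Threshold tibble from [bh_thresholds()] (or read from a
#'   supplementary table).
#' @param fdr_level FDR level to use when `thresholds` carries several.
#' @return Tibble with columns `condition`, `strain`, `direction`, `z`; a
#'   gene is a slow hit where `z <= z_threshold[slow]` and a fast hit where
#'   `z >= z_threshold[fast]`.
#' @export
call_hits <- function(gene_z, thresholds, fdr_level = 0.20) {
  thr <- thresholds[abs(thresholds$fdr_level - fdr_level) < 1e-9, ]
  missing_thr <- setdiff(unique(gene_z$condition), unique(thr$condition))
  if (length(missing_thr) > 0) {
    stop("no thresholds for condition(s): ",
         paste(missing_thr, collapse = ", "), call. = FALSE)
  }
  wide <- tidyr::pivot_wider(thr[, c("condition", "direction", "z_threshold")],
                             names_from = "direction",
                             values_from = "z_threshold")
  d <- dplyr::inner_join(gene_z, wide, by = "condition")
  slow <- d[!is.na(d$z) & d$z <= d$slow, c("condition", "strain", "z")]
  fast <- d[!is.na(d$z) & d$z >= d$fast, c("condition", "strain", "z")]
  out <- dplyr::bind_rows(
    dplyr::mutate(slow, direction = "slow"),
    dplyr::mutate(fast, direction = "fast")
  )
  dplyr::arrange(out[, c("condition", "strain", "direction", "z")],
                 .data$condition, .data$direction, .data$strain)
}

#' Per-condition hit counts
#'
#' Counts fast and slow hits per condition instance; with
#' `collapse_replicates = TRUE` the glucose:ammonium replicate instances are
#' averaged into a single (possibly fractional) count per nutrient pair, as
#' in the published per-condition summary.
#'
#' @param hits Tibble from [call_hits()].
#' @param collapse_replicates Average replicate instances per pair.
#' @param conditions Optional character vector of condition instances to
#'   report (conditions without hits get zero counts).
#' @return Tibble with columns `condition`, `fast`, `slow`.
#' @export
hit_counts <- function(hits, collapse_replicates = TRUE,
                       conditions = NULL) {
  counts <- hits |>
    dplyr::count(.data$condition, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  for (col in c("fast", "slow")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  if (!is.null(conditions)) {
    counts <- dplyr::left_join(tibble::tibble(condition = conditions),
                               counts, by = "condition")
    counts$fast[is.na(counts$fast)] <- 0L
    counts$slow[is.na(counts$slow)] <- 0L
  }
  if (!collapse_replicates) return(counts[, c("condition", "fast", "slow")])
  counts$pair <- condition_pair(counts$condition)
  counts |>
    dplyr::group_by(condition = .data$pair) |>
    dplyr::summarise(fast = mean(.data$fast), slow = mean(.data$slow),
                     .groups = "drop")
}

#' Count significant effects per gene
#'
#' For each gene, the number of distinct nutrient-pair conditions (outside
#' an excluded set) in which it is a slow (resp. fast) hit. Replicate
#' instances of the same pair count once.
#'
#' @param hits Tibble from [call_hits()].
#' @param exclude Character vector of `"carbon:nitrogen"` pair labels to
#'   exclude (default the reference condition).
#' @return Tibble with columns `strain`, `direction`, `n_conditions`.
#' @export
count_effects_per_gene <- function(hits, exclude = "glucose:ammonium") {
  h <- dplyr::mutate(hits, pair = condition_pair(.data$condition))
  h <- h[!h$pair %in% exclude, ]
  h |>
    dplyr::distinct(.data$strain, .data$direction, .data$pair) |>
    dplyr::count(.data$strain, .data$direction, name = "n_conditions")
}

#' Genes sensitive to a nutrient source across its pairings
#'
#' A gene is called sensitive to a source (galactose, say) when it is a
#' significant slow hit in at least `min_conditions` of the distinct
#' conditions involving that source --- the rule behind the published
#' galactose-sensitive gene set (at least 4 of the 7 galactose conditions).
#'
#' @param hits Tibble from [call_hits()].
#' @param source Carbon or nitrogen source name.
#' @param min_conditions Minimum distinct pairs with a hit.
#' @param direction `"slow"` (default) or `"fast"`.
#' @return Character vector of gene names, sorted.
#' @export
sensitive_genes <- function(hits, source, min_conditions = 4L,
                            direction = "slow") {
  h <- hits[hits$direction == direction, ]
  pc <- parse_condition(h$condition)
  h <- h[pc$carbon == source | pc$nitrogen == source, ]
  h$pair <- condition_pair(h$condition)
  tab <- h |>
    dplyr::distinct(.data$strain, .data$pair) |>
    dplyr::count(.data$strain)
  sort(tab$strain[tab$n >= min_conditions])
}
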