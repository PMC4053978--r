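#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline. Exactly one of
#' `colony_table` (path to a colony TSV) or `synthetic` (a
#' [synthetic_truth()] configuration) must be given.
#'
#' @param colony_table Optional path to a colony-area TSV.
#' @param synthetic Optional `cn_truth` synthetic configuration.
#' @param lowess_frac LOWESS window fraction (default 0.5).
#' @param gaussian_sigma Spatial filter SD in grid units (default 2).
#' @param spatial_smooth Apply the spatial filter between normalization and
#'   z-scoring (default `TRUE`).
#' @param fdr Hit-calling FDR level (default 0.20; thresholds are also
#'   computed at 0.10).
#' @param alpha Wild-type model per-term significance level (default 0.01).
#' @param nmf_iterations,nmf_cutoff NMF update count and membership cutoff.
#' @param top_n Genes kept for condition clustering (default 500).
#' @param min_overlap Minimum shared conditions for profile similarity.
#' @param null_min_n Minimum wild-type values per condition for the null.
#' @param seed Top-level seed; per-stage seeds derive from it.
#' @return A list of class `cn_config`.
#' @export
pipeline_config <- function(colony_table = NULL, synthetic = NULL,
                            lowess_frac = 0.5, gaussian_sigma = 2,
                            spatial_smooth = TRUE, fdr = 0.20, alpha = 0.01,
                            nmf_iterations = 20L, nmf_cutoff = 0.4,
                            top_n = 500L, min_overlap = 10L,
                            null_min_n = 100L, seed = 1L) {
  if (is.null(colony_table) == is.null(synthetic)) {
    stop("exactly one of colony_table or synthetic must be provided",
         call. = FALSE)
  }
  stopifnot(lowess_frac > 0, lowess_frac <= 1, gaussian_sigma > 0,
            fdr > 0, fdr < 1, alpha > 0, alpha < 1, nmf_iterations >= 1,
            nmf_cutoff >= 0, top_n >= 1, min_overlap >= 2)
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "cn_truth"))
  structure(as.list(environment()), class = "cn_config")
}

# per-stage seeds derive deterministically from the top-level seed
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 0L, nmf = 1L)
  (as.integer(seed) * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full screening pipeline
#'
#' Executes the stages in order: colony input (read or simulated), growth
#' rates, glucose:ammonium reference construction, LOWESS normalization,
#' spatial filtering, modified z-scores, wild-type null, BH thresholds
#' (FDR 10% and 20%), hit calling, the wild-type carbon-by-nitrogen
#' log-linear model, the fixed-coefficient NMF signature decomposition,
#' profile similarity and condition clustering. Every output is
#' reproducible from the configuration and its seed.
#'
#' Glycerol conditions contribute wild-type rates to the wild-type model
#' but are excluded from z-scoring and everything downstream of it: mutant
#' growth on glycerol is too slow and noisy to call effects.
#'
#' @param config A `cn_config` from [pipeline_config()].
#' @param out_dir Optional directory; when given, every artifact is written
#'   there as TSV together with a plain-text `manifest.txt` and `report.txt`.
#' @param profiles Compute the (large) gene-by-gene similarity matrix and
#'   condition clustering (default `TRUE`).
#' @return A list of artifacts: `rates`, `reference`, `normalized`,
#'   `zscores`, `gene_z`, `null`, `thresholds`, `hits`, `hit_counts`,
#'   `wt_model`, `nmf`, `signature_members`, `similarity`, `clustering`,
#'   `manifest` (and `experiment` for synthetic runs).
#' @export
run_pipeline <- function(config, out_dir = NULL, profiles = TRUE) {
  stopifnot(inherits(config, "cn_config"))

  if (!is.null(config$synthetic)) {
    experiment <- simulate_experiment(config$synthetic,
                                      seed = stage_seed(config$seed,
                                                        "simulate"))
    colonies <- experiment$colonies
    layout <- experiment$layout
  } else {
    experiment <- NULL
    colonies <- read_colony_table(config$colony_table)
    layout <- colonies |>
      dplyr::distinct(.data$plate, .data$row, .data$col, .data$strain) |>
      dplyr::mutate(is_wildtype = .data$strain == "WT")
    if (anyDuplicated(layout[, c("plate", "row", "col")])) {
      stop("conflicting strain layouts across plate sets", call. = FALSE)
    }
  }

  rates <- complete_rates(compute_growth_rates(colonies), layout)

  ga <- rates[condition_pair(rates$condition) == "glucose:ammonium" &
                parse_condition(rates$condition)$replicate > 0, ]
  reference <- build_reference(ga, lowess_frac = config$lowess_frac)

  scored <- rates[parse_condition(rates$condition)$carbon != "glycerol", ]
  normalized <- normalize_rates(scored, reference,
                                lowess_frac = config$lowess_frac)
  if (config$spatial_smooth) {
    normalized <- smooth_rates(normalized, sigma = config$gaussian_sigma)
  }

  zscores <- compute_zscores(normalized, reference)
  null <- fit_null(zscores, min_n = config$null_min_n)
  gene_z <- gene_zscores(zscores)
  thresholds <- bh_thresholds(gene_z, null, fdr = c(0.10, 0.20))
  hits <- call_hits(gene_z, thresholds, fdr_level = config$fdr)

  wt_rates <- rates[rates$is_wildtype & is.finite(rates$rate), ]
  wt_rates <- dplyr::bind_cols(wt_rates,
                               parse_condition(wt_rates$condition)[,
                                 c("carbon", "nitrogen")])
  wt_model <- fit_wt_model(wt_rates, alpha = config$alpha)

  nmf <- tryCatch(
    nmf_signatures(binarize_effects(gene_z, thresholds, fdr_level = 0.20),
                   iterations = config$nmf_iterations,
                   seed = stage_seed(config$seed, "nmf")),
    error = function(e) {
      warning("signature decomposition skipped: ", conditionMessage(e))
      NULL
    }
  )
  members <- if (is.null(nmf)) NULL else
    signature_members(nmf, cutoff = config$nmf_cutoff)

  similarity <- NULL
  clustering <- NULL
  if (profiles) {
    similarity <- profile_similarity(gene_z,
                                     min_overlap = config$min_overlap)
    n_genes <- length(unique(gene_z$strain))
    clustering <- cluster_conditions(gene_z,
                                     top_n = min(config$top_n, n_genes))
  }

  manifest <- tibble::tibble(
    parameter = c("seed", "lowess_frac", "gaussian_sigma", "spatial_smooth",
                  "fdr", "alpha", "nmf_iterations", "nmf_cutoff", "top_n",
                  "min_overlap", "input", "package_version", "r_version"),
    value = c(config$seed, config$lowess_frac, config$gaussian_sigma,
              config$spatial_smooth, config$fdr, config$alpha,
              config$nmf_iterations, config$nmf_cutoff, config$top_n,
              config$min_overlap,
              if (is.null(config$colony_table)) "synthetic" else
                config$colony_table,
              as.character(utils::packageVersion("cnscreen")),
              as.character(getRversion()))
  )

  artifacts <- list(
    experiment = experiment, rates = rates, reference = reference,
    normalized = normalized, zscores = zscores, gene_z = gene_z,
    null = null, thresholds = thresholds, hits = hits,
    hit_counts = hit_counts(hits, conditions = unique(gene_z$condition)),
    wt_model = wt_model, nmf = nmf,
    signature_members = members, similarity = similarity,
    clustering = clustering, manifest = manifest
  )
  if (!is.null(out_dir)) write_artifacts(artifacts, out_dir)
  artifacts
}

write_artifacts <- function(a, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  write_rate_matrix(a$rates[, c("strain", "condition", "rate")] |>
                      dplyr::group_by(.data$strain, .data$condition) |>
                      dplyr::summarise(rate = mean(.data$rate, na.rm = TRUE),
                                       .groups = "drop"),
                    path("rates.tsv"))
  readr::write_tsv(a$reference, path("reference.tsv"), progress = FALSE)
  write_rate_matrix(a$gene_z, path("zscores.tsv"), value = "z")
  readr::write_tsv(a$null, path("null.tsv"), progress = FALSE)
  readr::write_tsv(a$thresholds, path("thresholds.tsv"), progress = FALSE)
  readr::write_tsv(a$hits, path("hits.tsv"), progress = FALSE)
  readr::write_tsv(a$hit_counts, path("hit_counts.tsv"), progress = FALSE)
  readr::write_tsv(tidy(a$wt_model), path("wt_model_terms.tsv"),
                   progress = FALSE)
  if (!is.null(a$nmf)) {
    readr::write_tsv(tidy(a$nmf), path("signatures.tsv"), progress = FALSE)
    readr::write_tsv(a$nmf$error, path("nmf_error.tsv"), progress = FALSE)
    mem <- tibble::tibble(
      source = rep(names(a$signature_members),
                   lengths(a$signature_members)),
      gene = unlist(a$signature_members, use.names = FALSE)
    )
    readr::write_tsv(mem, path("signature_members.tsv"), progress = FALSE)
  }
  readr::write_tsv(a$manifest, path("manifest.txt"), progress = FALSE)

  counts <- a$hit_counts
  report <- c(
    "screen pipeline report",
    sprintf("conditions scored: %d", length(unique(a$gene_z$condition))),
    sprintf("genes scored: %d", length(unique(a$gene_z$strain))),
    "per-condition hits (fast/slow, replicates averaged):",
    sprintf("  %s: %.1f/%.1f", counts$condition, counts$fast, counts$slow),
    sprintf("wild-type model: %d interaction terms, %d non-significant",
            sum(a$wt_model$terms$type == "interaction"),
            nrow(independent_conditions(a$wt_model)))
  )
  if (!is.null(a$signature_members)) {
    gal_rib <- length(intersect(a$signature_members$galactose,
                                a$signature_members$ribose))
    report <- c(report,
                sprintf("galactose/ribose signature overlap: %d genes",
                        gal_rib))
  }
  writeLines(report, path("report.txt"))
  invisible(out_dir)
}
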