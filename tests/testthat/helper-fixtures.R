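# Small experiment configurations used across test files. Plates are 8 x 12
# (96-format) so six-replicate reference building and the wild-type scatter
# still work at a fraction of the genome-wide array size.

small_truth <- function(...) {
  args <- list(...)
  defaults <- list(
    n_plates = 4L, n_rows = 8L, n_cols = 12L,
    n_mutants = 200L, n_wildtype = 120L,
    n_slow = 20L, n_fast = 5L
  )
  do.call(synthetic_truth, utils::modifyList(defaults, args))
}

# a deterministic colony table with a handful of colonies, written to a
# temp TSV; returns the path
write_tiny_colony_tsv <- function(path = tempfile(fileext = ".tsv")) {
  tab <- tibble::tibble(
    plate = c(1L, 1L, 1L, 1L, 1L, 1L),
    row = c(1L, 1L, 1L, 2L, 2L, 2L),
    col = 1L,
    strain = c("mutA", "mutA", "mutA", "WT", "WT", "WT"),
    carbon = "glucose", nitrogen = "proline", replicate = 0L,
    time_s = c(0, 18000, 36000, 0, 18000, 36000),
    area_px = c(50, 140, 230, 50, 120, 190)
  )
  readr::write_tsv(tab, path, progress = FALSE)
  path
}

# brute-force Pearson over jointly finite entries for two profile vectors
naive_pairwise_pearson <- function(m) {
  g <- nrow(m)
  out <- matrix(NA_real_, g, g, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      ok <- is.finite(m[i, ]) & is.finite(m[j, ])
      out[i, j] <- if (sum(ok) >= 2)
        suppressWarnings(stats::cor(m[i, ok], m[j, ok])) else NA_real_
    }
  }
  out
}

# exhaustive BH step-up oracle: sort, walk down, reject all at or below the
# largest passing index
bh_oracle <- function(p, alpha) {
  ok <- which(is.finite(p))
  m <- length(ok)
  if (m == 0) return(rep(FALSE, length(p)))
  ord <- ok[order(p[ok])]
  k <- 0
  for (i in seq_len(m)) {
    if (p[ord[i]] <= i / m * alpha) k <- i
  }
  rej <- rep(FALSE, length(p))
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# wild-type replicate rates on the full carbon x nitrogen grid with known
# log-scale effects (gamma: named interaction terms on "carbon:nitrogen")
wt_grid_rates <- function(n_rep, mu, alpha_c, beta_n, gamma = NULL,
                          noise_sd = 0, seed = 41) {
  set.seed(seed)
  grid <- tidyr::expand_grid(carbon = names(alpha_c),
                             nitrogen = names(beta_n))
  d <- tidyr::expand_grid(grid, rep = seq_len(n_rep))
  logr <- mu + alpha_c[d$carbon] + beta_n[d$nitrogen]
  if (!is.null(gamma)) {
    key <- paste0(d$carbon, ":", d$nitrogen)
    logr <- logr + ifelse(key %in% names(gamma), gamma[key], 0)
  }
  d$rate <- exp(logr + stats::rnorm(nrow(d), 0, noise_sd))
  d
}
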