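make_zscore_fixture <- function(seed = 31, n_slow = 15, n_fast = 5) {
  exper <- simulate_experiment(
    small_truth(n_slow = n_slow, n_fast = n_fast,
                conditions = c("glucose:ammonium", "galactose:urea",
                               "ribose:proline", "glucose:proline")),
    seed = seed
  )
  rates <- complete_rates(compute_growth_rates(exper$colonies),
                          exper$layout)
  ga <- rates[parse_condition(rates$condition)$replicate > 0, ]
  ref <- build_reference(ga)
  norm <- smooth_rates(normalize_rates(rates, ref))
  z <- compute_zscores(norm, ref)
  list(exper = exper, rates = rates, ref = ref, z = z)
}

test_that("the z formula combines residual, strain SD and plate SD", {
  # hand evaluation: residual 0.02, sd_strain 0.03, sd_plate 0.04 -> z 0.4
  expect_equal(0.02 / sqrt(0.03^2 + 0.04^2), 0.4)
  fx <- make_zscore_fixture()
  d <- fx$z[is.finite(fx$z$z), ]
  joined <- dplyr::inner_join(
    d, fx$ref[, c("plate", "row", "col", "strain_sd")],
    by = c("plate", "row", "col")
  )
  expect_equal(joined$z,
               joined$residual / sqrt(joined$strain_sd^2 + joined$plate_sd^2),
               tolerance = 1e-12)
  # a cell is missing iff residual (normalized or reference rate) is missing
  expect_identical(is.na(fx$z$z), is.na(fx$z$residual))
})

test_that("zero combined variance raises the undefined-z guard", {
  norm <- tidyr::expand_grid(condition = "galactose:urea", plate = 1L,
                             row = 1:4, col = 1:4)
  norm$strain <- paste0("s", seq_len(nrow(norm)))
  norm$is_wildtype <- FALSE
  norm$norm_rate <- 0.02
  ref <- norm[, c("plate", "row", "col")]
  ref$ga_ref <- 0.02
  ref$strain_sd <- 0
  expect_error(compute_zscores(norm, ref), "zero combined variance")
  # with positive strain SD the same data give all-zero z
  ref$strain_sd <- 0.01
  z <- compute_zscores(norm, ref)
  expect_equal(z$z, rep(0, nrow(z)))
})

test_that("wild-type null fitting uses only wild-type positions", {
  fx <- make_zscore_fixture()
  null <- fit_null(fx$z, min_n = 50)
  expect_true(all(null$sd > 0))
  expect_true(all(null$n >= 50))
  # mean of the wild-type z is near 0 after normalization to the reference
  expect_lt(max(abs(null$mean)), 0.2)
  # mutant z values cannot influence the null
  z2 <- fx$z
  z2$z[!z2$is_wildtype] <- z2$z[!z2$is_wildtype] + 100
  expect_equal(fit_null(z2, min_n = 50), null)
  # degenerate null is rejected
  z3 <- fx$z
  z3$z[z3$is_wildtype] <- 0.2
  expect_error(fit_null(z3, min_n = 50), "positive")
  expect_error(fit_null(fx$z[1:30, ], min_n = 50), "insufficient")
})

test_that("BH step-up matches the exhaustive oracle on random inputs", {
  set.seed(32)
  for (i in 1:40) {
    m <- sample(c(5, 50, 1000), 1)
    p <- runif(m)^sample(1:3, 1) # occasionally enriched near 0
    if (i %% 4 == 0) p[sample(m, 2)] <- NA
    alpha <- sample(c(0.05, 0.1, 0.2), 1)
    expect_identical(bh_reject(p, alpha), bh_oracle(p, alpha))
  }
  # spiked example: 990 null + 10 extreme are all recovered
  set.seed(33)
  z <- c(rnorm(990), rep(-8, 10))
  p <- pnorm(z)
  rej <- bh_reject(p, 0.20)
  expect_identical(rej, bh_oracle(p, 0.20))
  expect_true(all(rej[991:1000]))
  # cross-check against the stats implementation
  expect_identical(unname(which(rej)),
                   unname(which(p.adjust(p, "BH") <= 0.20)))
})

test_that("thresholds delimit the BH rejection region per condition", {
  fx <- make_zscore_fixture()
  null <- fit_null(fx$z, min_n = 50)
  gz <- gene_zscores(fx$z)
  thr <- bh_thresholds(gz, null, fdr = c(0.10, 0.20))
  # slow thresholds <= 0 <= fast thresholds (finite ones)
  slow <- thr$z_threshold[thr$direction == "slow" & is.finite(thr$z_threshold)]
  fast <- thr$z_threshold[thr$direction == "fast" & is.finite(thr$z_threshold)]
  expect_true(all(slow <= 0))
  expect_true(all(fast >= 0))
  # stricter FDR gives at least as extreme thresholds
  wide <- tidyr::pivot_wider(thr, names_from = "fdr_level",
                             values_from = c("z_threshold", "n_rejected"))
  expect_true(all(abs(wide$`z_threshold_0.1`) >= abs(wide$`z_threshold_0.2`) |
                    !is.finite(wide$`z_threshold_0.1`)))
  # hits called from thresholds reproduce the BH rejection sets
  hits <- call_hits(gz, thr, fdr_level = 0.20)
  for (cond in unique(gz$condition)) {
    z <- gz$z[gz$condition == cond]
    nu <- null[null$condition == cond, ]
    rej_slow <- bh_reject(pnorm(z, nu$mean, nu$sd), 0.20)
    called <- gz$strain[gz$condition == cond][rej_slow]
    listed <- hits$strain[hits$condition == cond & hits$direction == "slow"]
    expect_setequal(called, listed)
  }
})

test_that("hit calling is monotone and antisymmetric", {
  gz <- tibble::tibble(
    strain = rep(paste0("g", 1:6), 2),
    condition = rep(c("galactose:urea", "ribose:proline"), each = 6),
    z = c(-5, -2, -0.5, 0.4, 2.2, 6, -4, -1, 0, 1, 3, 5)
  )
  thr <- tidyr::expand_grid(condition = unique(gz$condition),
                            direction = c("fast", "slow"), fdr_level = 0.2)
  thr$z_threshold <- ifelse(thr$direction == "slow", -1.5, 2.0)
  thr$n_rejected <- NA_integer_
  hits <- call_hits(gz, thr)
  expect_setequal(hits$strain[hits$direction == "slow" &
                                hits$condition == "galactose:urea"],
                  c("g1", "g2"))
  # negating z swaps the lists (with thresholds mirrored)
  gz_neg <- gz
  gz_neg$z <- -gz$z
  thr_neg <- thr
  thr_neg$z_threshold <- ifelse(thr_neg$direction == "slow", -2.0, 1.5)
  hits_neg <- call_hits(gz_neg, thr_neg)
  expect_setequal(
    hits_neg$strain[hits_neg$direction == "fast" &
                      hits_neg$condition == "galactose:urea"],
    hits$strain[hits$direction == "slow" &
                  hits$condition == "galactose:urea"])
  # making a z more extreme never removes it from a hit list
  gz2 <- gz
  gz2$z[gz2$strain == "g2"] <- gz2$z[gz2$strain == "g2"] - 10
  hits2 <- call_hits(gz2, thr)
  was_hit <- unique(paste(hits$strain, hits$condition, hits$direction))
  now_hit <- unique(paste(hits2$strain, hits2$condition, hits2$direction))
  expect_true(all(setdiff(was_hit, now_hit) %in%
                    paste("g2", gz$condition, "fast")))
  # an empty z matrix yields an empty hit table
  expect_equal(nrow(call_hits(gz[0, ], thr)), 0)
})

test_that("per-gene effect counting respects the exclusion set", {
  hits <- tibble::tibble(
    condition = c("glucose:ammonium01", "glucose:ammonium02",
                  "galactose:urea", "ribose:proline", "glucose:proline",
                  "galactose:urea"),
    strain = c("g1", "g1", "g1", "g1", "g2", "g2"),
    direction = "slow", z = -3
  )
  counts <- count_effects_per_gene(hits)
  expect_equal(counts$n_conditions[counts$strain == "g1"], 2)
  expect_equal(counts$n_conditions[counts$strain == "g2"], 2)
  # the replicate instances count as one pair when not excluded
  counts_all <- count_effects_per_gene(hits, exclude = character())
  expect_equal(counts_all$n_conditions[counts_all$strain == "g1"], 3)
})

test_that("source-sensitive gene calling uses distinct pair counts", {
  hits <- tibble::tibble(
    condition = c("galactose:urea", "galactose:proline",
                  "galactose:ammonium", "galactose:arginine",
                  "galactose:urea", "ribose:urea"),
    strain = c("g1", "g1", "g1", "g1", "g2", "g2"),
    direction = "slow", z = -3
  )
  expect_equal(sensitive_genes(hits, "galactose", min_conditions = 4), "g1")
  expect_equal(sensitive_genes(hits, "galactose", min_conditions = 1),
               c("g1", "g2"))
  expect_equal(sensitive_genes(hits, "urea", min_conditions = 2), "g2")
})

test_that("randomized hit assignment preserves per-condition counts", {
  # permutation control: redistribute each condition's hits uniformly over
  # genes and compare the per-gene count distribution to a binomial draw
  set.seed(34)
  genes <- paste0("g", 1:300)
  conds <- c("galactose:urea", "ribose:proline", "glucose:proline")
  n_hits <- c(40, 60, 30)
  draws <- purrr::map(1:200, function(i) {
    h <- purrr::map2(conds, n_hits, function(cc, n) {
      tibble::tibble(condition = cc, strain = sample(genes, n),
                     direction = "slow", z = -3)
    }) |> dplyr::bind_rows()
    counts <- count_effects_per_gene(h, exclude = character())
    tabulate(counts$n_conditions, nbins = 3)
  })
  mean_counts <- Reduce(`+`, draws) / length(draws)
  # expected from independent inclusion probabilities 40/300, 60/300, 30/300
  p <- n_hits / length(genes)
  poly <- c(
    sum(p * c((1 - p[2]) * (1 - p[3]), (1 - p[1]) * (1 - p[3]),
              (1 - p[1]) * (1 - p[2]))),
    p[1] * p[2] * (1 - p[3]) + p[1] * p[3] * (1 - p[2]) +
      p[2] * p[3] * (1 - p[1]),
    prod(p)
  ) * length(genes)
  expect_equal(mean_counts, poly, tolerance = 0.05)
})
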