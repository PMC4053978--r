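test_that("profile similarity equals the brute-force Pearson oracle", {
  set.seed(61)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  s <- profile_similarity(m, min_overlap = 2)
  expect_equal(s, naive_pairwise_pearson(m), tolerance = 1e-12,
               ignore_attr = FALSE)
  expect_equal(unname(diag(s)), rep(1, 20))
  # perfect anticorrelation
  m2 <- rbind(x = m[1, ], y = -m[1, ])
  s2 <- profile_similarity(m2, min_overlap = 2)
  expect_equal(unname(s2["x", "y"]), -1, tolerance = 1e-12)
  # pairs under the overlap threshold are undefined
  m3 <- m
  m3[2, 1:6] <- NA
  s3 <- profile_similarity(m3, min_overlap = 5)
  expect_true(is.na(s3["g2", "g1"]))
})

test_that("precision-recall follows the hand-computed example", {
  # 5 pairs, co-annotated pairs ranked 1st and 3rd
  sim <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  sim["a", "b"] <- 0.9 # co-annotated
  sim["a", "c"] <- 0.8
  sim["a", "d"] <- 0.7 # co-annotated
  sim["b", "c"] <- 0.6
  sim["b", "d"] <- 0.5
  sim["c", "d"] <- NA
  sim[lower.tri(sim)] <- t(sim)[lower.tri(sim)]
  diag(sim) <- 1
  sets <- list(t1 = c("a", "b"), t2 = c("a", "d"))
  pr <- precision_recall(sim, sets, min_pairs = 2)
  expect_equal(pr$precision, c(1, 0.5, 2 / 3, 0.5, 0.4), tolerance = 1e-12)
  expect_equal(pr$recall, c(1, 1, 2, 2, 2))
  # precision at full recall equals the background rate exactly
  expect_equal(pr$precision[nrow(pr)], pr$background[1])
})

test_that("perfect rankings give precision 1 and shuffles match background", {
  set.seed(62)
  genes <- paste0("g", 1:30)
  sets <- list(grp = genes[1:10]) # 45 co-annotated pairs
  base <- matrix(0, 30, 30, dimnames = list(genes, genes))
  co <- combn(genes[1:10], 2)
  sim <- base
  sim[upper.tri(sim)] <- runif(sum(upper.tri(sim)), 0, 0.5)
  sim <- pmax(sim, t(sim))
  sim[cbind(co[1, ], co[2, ])] <- runif(ncol(co), 0.8, 1)
  sim <- pmax(sim, t(sim))
  diag(sim) <- 1
  pr <- precision_recall(sim, sets, min_pairs = 10)
  k <- ncol(co)
  expect_equal(pr$precision[seq_len(k)], rep(1, k))

  # random scores: precision at moderate rank stays near background
  precs <- purrr::map_dbl(1:50, function(i) {
    s <- base
    s[upper.tri(s)] <- runif(sum(upper.tri(s)))
    s <- pmax(s, t(s))
    diag(s) <- 1
    p <- precision_recall(s, sets, min_pairs = 10)
    p$precision[100]
  })
  bg <- choose(10, 2) / choose(30, 2)
  sd_bin <- sqrt(bg * (1 - bg) / 100)
  expect_lt(abs(mean(precs) - bg), 3 * sd_bin)
})

test_that("condition clustering finds planted carbon blocks", {
  set.seed(63)
  conds <- condition_grid(1)
  conds <- conds[conds$carbon != "glycerol", ]
  carbon_sig <- purrr::map(unique(conds$carbon), ~ rnorm(120, 0, 2))
  names(carbon_sig) <- unique(conds$carbon)
  m <- vapply(seq_len(nrow(conds)),
              function(j) carbon_sig[[conds$carbon[j]]] + rnorm(120, 0, 0.5),
              numeric(120))
  dimnames(m) <- list(paste0("g", 1:120), conds$condition)
  cl <- cluster_conditions(m, top_n = 100)
  groups <- cutree(cl$conditions, k = 3)
  expect_equal(length(unique(tapply(conds$carbon, groups,
                                    function(x) paste(sort(unique(x)))))), 3)
  for (g in unique(groups)) {
    expect_length(unique(conds$carbon[groups == g]), 1)
  }
  # identical columns merge at height 0 first
  m2 <- cbind(m[, 1, drop = FALSE],
              `glucose:proline` = m[, 1], `glucose:urea` = m[, 1])
  cl2 <- cluster_conditions(m2, top_n = 50)
  expect_equal(cl2$conditions$height[1:2], c(0, 0), tolerance = 1e-12)
  expect_error(cluster_conditions(m, top_n = 1000), "top_n")
})

test_that("hypergeometric overlap matches closed forms and enumeration", {
  # closed form: N=5, |A|=|B|=2, overlap 2 -> 1/C(5,2)
  h <- hypergeometric_overlap(c("a", "b"), c("a", "b"), 5)
  expect_equal(h$p.value, 1 / choose(5, 2), tolerance = 1e-12)
  # disjoint sets that cannot overlap give p = 1
  h0 <- hypergeometric_overlap(c("a", "b"), c("c", "d"), 4)
  expect_equal(h0$p.value, 1)
  # brute-force enumeration oracle for N <= 12
  set.seed(64)
  universe <- paste0("u", 1:10)
  for (i in 1:20) {
    a <- sample(universe, sample(1:8, 1))
    b <- sample(universe, sample(1:8, 1))
    obs <- length(intersect(a, b))
    combos <- combn(universe, length(b))
    olap <- apply(combos, 2, function(s) length(intersect(a, s)))
    expect_equal(hypergeometric_overlap(a, b, 10)$p.value,
                 mean(olap >= obs), tolerance = 1e-12)
  }
  expect_error(hypergeometric_overlap(universe, "u1", 5), "universe")
})

test_that("enrichment composes hypergeometric tests with Bonferroni", {
  bg <- paste0("g", 1:50)
  sets <- list(t1 = bg[1:10], t2 = bg[5:20], t3 = bg[40:50])
  genes <- bg[1:10]
  enr <- term_enrichment(genes, sets, bg)
  for (i in seq_len(nrow(enr))) {
    raw <- hypergeometric_overlap(sets[[enr$term[i]]], genes, 50)$p.value
    expect_equal(enr$p.value[i], raw, tolerance = 1e-12)
    expect_equal(enr$p.adjusted[i], min(raw * 3, 1), tolerance = 1e-12)
  }
  one <- term_enrichment(genes, sets["t1"], bg)
  expect_equal(one$p.adjusted, one$p.value)
  expect_error(term_enrichment(genes, sets, character()), "background")
})

test_that("the sign test matches exact binomial tails", {
  z <- tidyr::expand_grid(strain = paste0("g", 1:9),
                          condition = paste0("galactose:",
                                             nitrogen_sources()))
  z$z <- -1
  z2 <- tidyr::expand_grid(strain = paste0("g", 1:9),
                           condition = paste0("ribose:",
                                              nitrogen_sources()))
  z2$z <- 1
  zz <- dplyr::bind_rows(z, z2)
  res <- gene_set_sign_test(zz, paste0("g", 1:9),
                            group_a = unique(z$condition),
                            group_b = unique(z2$condition))
  expect_equal(res$n_matching, 14)
  expect_equal(res$p.value, 0.5^14, tolerance = 1e-12)
  expect_equal(res$p.value, 6.10e-5, tolerance = 1e-3)

  # partial match: exact binomial tail oracle
  zz2 <- zz
  zz2$z[zz2$condition %in% unique(z$condition)[1:7]] <- 1 # 7 of 14 match
  res2 <- gene_set_sign_test(zz2, paste0("g", 1:9),
                             group_a = unique(z$condition),
                             group_b = unique(z2$condition))
  expect_equal(res2$n_matching, 7)
  expect_equal(res2$p.value, sum(dbinom(7:14, 14, 0.5)), tolerance = 1e-12)
  expect_equal(res2$p.value, 0.6047, tolerance = 1e-3)

  # group B may be empty
  res3 <- gene_set_sign_test(zz, paste0("g", 1:9),
                             group_a = unique(z$condition))
  expect_equal(res3$p.value, 0.5^7, tolerance = 1e-12)
})

test_that("cross-profile similarity normalizes to unit lengths", {
  set.seed(65)
  genes <- paste0("g", 1:150)
  env <- matrix(rnorm(10 * 150), 10, 150,
                dimnames = list(paste0("cond", 1:10), genes))
  qry <- matrix(rnorm(30 * 150), 30, 150,
                dimnames = list(paste0("q", 1:30), genes))
  env[sample(length(env), 50)] <- NA
  # on a square matrix both row and column norms settle within 1 +/- 0.05
  sq <- matrix(rnorm(50 * 50), 50, 50)
  asq <- bidirectional_normalize(sq)
  expect_true(all(abs(sqrt(rowSums(asq^2)) - 1) < 0.05))
  expect_true(all(abs(sqrt(colSums(asq^2)) - 1) < 0.05))
  # rectangular input: rows exactly unit, column norms equalized (a global
  # scale that cannot change similarity rankings)
  a <- bidirectional_normalize(env)
  expect_true(all(abs(sqrt(rowSums(a^2)) - 1) < 1e-6))
  cn <- sqrt(colSums(a^2))
  expect_lt(stats::sd(cn) / mean(cn), 0.35)
  res <- cross_profile_similarity(env, qry, min_shared = 100)
  expect_equal(dim(res$similarity), c(10, 30))
  expect_length(res$top_queries[["cond1"]], 3)
  # swapping inputs transposes the similarity
  res_t <- cross_profile_similarity(qry, env, min_shared = 100)
  expect_equal(res_t$similarity, t(res$similarity), tolerance = 1e-12)
  # a query equal to a condition profile attains its maximum
  qry2 <- rbind(qry, clone = env[3, ])
  qry2[is.na(qry2)] <- 0
  res2 <- cross_profile_similarity(env, qry2, min_shared = 100)
  expect_equal(names(which.max(res2$similarity["cond3", ])), "clone")
  expect_error(cross_profile_similarity(env[, 1:50], qry[, 1:50]),
               "shared gene universe")
})

test_that("planted cross-profile matches land in the top decile", {
  set.seed(66)
  genes <- paste0("g", 1:200)
  hits <- 0
  n_seeds <- 60
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    sig <- rnorm(200)
    env <- rbind(target = sig + rnorm(200, 0, 0.4),
                 other1 = rnorm(200), other2 = rnorm(200))
    colnames(env) <- genes
    qry <- matrix(rnorm(40 * 200), 40, 200,
                  dimnames = list(paste0("q", 1:40), genes))
    qry["q1", ] <- sig + rnorm(200, 0, 0.4) # shares the planted signature
    res <- cross_profile_similarity(env, qry, min_shared = 100)
    if ("q1" %in% res$top_queries[["target"]]) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("liquid growth scoring follows the saturation formula", {
  # OD reaching its max 1.0 at 10 h scores 0.1 per hour
  expect_equal(liquid_growth_rate(c(0, 2, 10, 12), c(0.05, 0.3, 1, 1)),
               0.1)
  expect_true(is.na(liquid_growth_rate(5, 1)))

  mk <- function(strain, cond, factor) {
    tidyr::expand_grid(strain = strain, condition = cond,
                       well = 1:2, time_h = c(0, 5, 10, 20)) |>
      dplyr::mutate(od = pmin(0.1 * .data$time_h * factor, 1))
  }
  conds <- c("glucose:ammonium", "galactose:urea", "ribose:proline")
  wt <- purrr::map(conds, ~ mk("WT", .x, 1)) |> dplyr::bind_rows()
  # mutant is half speed in galactose:urea only
  mut <- dplyr::bind_rows(mk("m1", "glucose:ammonium", 1),
                          mk("m1", "galactose:urea", 0.5),
                          mk("m1", "ribose:proline", 1))
  sc <- liquid_adjusted_score(mut, wt)
  expect_equal(sc$adjusted_score[sc$condition == "glucose:ammonium"], 1,
               tolerance = 1e-9)
  expect_equal(sc$adjusted_score[sc$condition == "ribose:proline"], 1,
               tolerance = 1e-9)
  expect_lt(sc$adjusted_score[sc$condition == "galactose:urea"], 0.75)
  # identical mutant scores 1 everywhere
  mut2 <- wt |> dplyr::mutate(strain = "m2")
  sc2 <- liquid_adjusted_score(mut2, wt)
  expect_equal(sc2$adjusted_score, rep(1, 3), tolerance = 1e-9)
})
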