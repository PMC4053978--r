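#' Gene-by-gene profile similarity
#'
#' Pairwise Pearson correlation of sensitivity profiles over jointly finite
#' conditions. Pairs sharing fewer than `min_overlap` conditions are
#' undefined (NA): with about 21 scored conditions, shorter overlaps make
#' correlations unstable.
#'
#' @param gene_z Gene-level z tibble from [gene_zscores()], or a numeric
#'   genes-by-conditions matrix.
#' @param min_overlap Minimum number of shared finite conditions.
#' @return Symmetric genes-by-genes correlation matrix with unit diagonal.
#' @export
profile_similarity <- function(gene_z, min_overlap = 10L) {
  m <- as_gene_matrix(gene_z, "z")
  if (ncol(m) < 2) stop("at least 2 conditions are required", call. = FALSE)
  s <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  overlap <- crossprod(t(!is.na(m)) * 1)
  s[overlap < min_overlap] <- NA_real_
  diag(s) <- 1
  s
}

as_gene_matrix <- function(gene_z, value = "z") {
  if (is.matrix(gene_z)) return(gene_z)
  stopifnot(all(c("strain", "condition", value) %in% names(gene_z)))
  wide <- tidyr::pivot_wider(gene_z[, c("strain", "condition", value)],
                             names_from = "condition",
                             values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$strain
  m
}

#' Precision-recall of co-annotation against profile similarity
#'
#' Ranks all unordered gene pairs by profile similarity (descending; ties
#' broken by the lexicographic order of the pair identifiers so the curve
#' is deterministic) and computes cumulative precision and recall against a
#' co-annotation standard: a pair is positive when both genes share at
#' least one annotation term. The background rate is the co-annotation rate
#' among all evaluable pairs; precision at full recall equals it exactly.
#'
#' @param similarity Matrix from [profile_similarity()].
#' @param term_sets Named list of gene sets (see [read_gene_sets()]).
#' @param gene_subset Optional character vector restricting the evaluation.
#' @param min_pairs Minimum number of evaluable pairs.
#' @return Tibble with one row per rank: `rank`, `gene1`, `gene2`,
#'   `similarity`, `co_annotated`, `precision`, `recall`, and a
#'   `background` attribute column (constant).
#' @export
precision_recall <- function(similarity, term_sets, gene_subset = NULL,
                             min_pairs = 100L) {
  genes <- rownames(similarity)
  if (!is.null(gene_subset)) genes <- intersect(genes, gene_subset)
  genes <- sort(genes)
  if (length(genes) < 2) stop("fewer than 2 genes to evaluate", call. = FALSE)
  s <- similarity[genes, genes, drop = FALSE]
  idx <- which(upper.tri(s), arr.ind = TRUE)
  pairs <- tibble::tibble(
    gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
    similarity = s[idx]
  )
  pairs <- pairs[is.finite(pairs$similarity), ]
  if (nrow(pairs) < min_pairs) {
    stop("only ", nrow(pairs), " evaluable gene pairs (need ", min_pairs,
         ")", call. = FALSE)
  }
  co <- co_annotated(pairs$gene1, pairs$gene2, term_sets)
  pairs$co_annotated <- co
  ord <- order(-pairs$similarity, pairs$gene1, pairs$gene2)
  pairs <- pairs[ord, ]
  pairs$rank <- seq_len(nrow(pairs))
  pairs$precision <- cumsum(pairs$co_annotated) / pairs$rank
  pairs$recall <- cumsum(pairs$co_annotated)
  pairs$background <- mean(pairs$co_annotated)
  pairs[, c("rank", "gene1", "gene2", "similarity", "co_annotated",
            "precision", "recall", "background")]
}

co_annotated <- function(gene1, gene2, term_sets) {
  genes <- sort(unique(c(gene1, gene2)))
  member <- vapply(term_sets, function(s) genes %in% s,
                   logical(length(genes)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(genes))
  shared <- tcrossprod(member * 1) > 0
  dimnames(shared) <- list(genes, genes)
  shared[cbind(gene1, gene2)]
}

#' Hierarchical clustering of conditions and genes
#'
#' Retains the `top_n` genes with the highest profile variance and
#' agglomeratively clusters both conditions and genes on correlation
#' distance (1 - Pearson).
#'
#' @param gene_z Gene-level z tibble or matrix (see [profile_similarity()]).
#' @param top_n Number of highest-variance genes to keep (default 500).
#' @param method Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return List with elements `conditions` and `genes` (both `hclust`) and
#'   `matrix` (the filtered gene-by-condition matrix).
#' @export
cluster_conditions <- function(gene_z, top_n = 500L, method = "average") {
  m <- as_gene_matrix(gene_z, "z")
  v <- apply(m, 1, stats::var, na.rm = TRUE)
  if (top_n > nrow(m)) {
    stop("top_n exceeds the number of genes (", nrow(m), ")", call. = FALSE)
  }
  m <- m[order(-v)[seq_len(top_n)], , drop = FALSE]
  cor_dist <- function(x) {
    s <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    s[!is.finite(s)] <- 0
    stats::as.dist(1 - s)
  }
  list(
    conditions = stats::hclust(cor_dist(m), method = method),
    genes = stats::hclust(cor_dist(t(m)), method = method),
    matrix = m
  )
}

#' Hypergeometric overlap of two gene sets
#'
#' Upper-tail probability of drawing at least the observed overlap when
#' `|B|` genes are sampled without replacement from a universe containing
#' `|A|` marked genes.
#'
#' @param set_a,set_b Character vectors of genes.
#' @param universe_size Size of the common gene universe.
#' @return Tibble with `overlap`, `size_a`, `size_b`, `universe`,
#'   `p.value`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) > universe_size || length(set_b) > universe_size) {
    stop("sets cannot exceed the universe", call. = FALSE)
  }
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a), universe_size - length(set_a),
                     length(set_b), lower.tail = FALSE)
  tibble::tibble(overlap = k, size_a = length(set_a),
                 size_b = length(set_b), universe = universe_size,
                 p.value = p)
}

#' Term enrichment with Bonferroni correction
#'
#' Hypergeometric enrichment of a gene list against each term's gene set
#' over a stated background; raw p-values are multiplied by the number of
#' terms tested and capped at 1.
#'
#' @param gene_list Character vector of genes of interest.
#' @param term_sets Named list of gene sets.
#' @param background Character vector: the background gene universe
#'   (must contain `gene_list`).
#' @return Tibble with one row per term: `term`, `overlap`, `term_size`,
#'   `p.value`, `p.adjusted`, sorted by adjusted p.
#' @export
term_enrichment <- function(gene_list, term_sets, background) {
  if (length(background) == 0) stop("empty background", call. = FALSE)
  stopifnot(all(gene_list %in% background))
  gene_list <- unique(gene_list)
  n_terms <- length(term_sets)
  rows <- purrr::imap(term_sets, function(genes, term) {
    genes <- intersect(unique(genes), background)
    h <- hypergeometric_overlap(genes, gene_list, length(background))
    tibble::tibble(term = term, overlap = h$overlap,
                   term_size = length(genes), p.value = h$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p.adjusted <- pmin(out$p.value * n_terms, 1)
  dplyr::arrange(out, .data$p.adjusted, .data$p.value)
}

#' Sign test for a gene set's median z across condition groups
#'
#' Computes the per-condition median z over a gene set and tests the sign
#' pattern "negative in group A, positive in group B" with an exact
#' binomial tail at success probability 1/2 (a median has no a priori sign
#' preference under the null). Fourteen matches out of fourteen conditions
#' give p = 0.5^14.
#'
#' @param gene_z Gene-level z tibble or matrix.
#' @param gene_set Character vector of genes.
#' @param group_a Conditions hypothesized to have negative medians.
#' @param group_b Conditions hypothesized to have positive medians (may be
#'   empty, in which case only group A is tested).
#' @return List with `medians` (tibble of condition, group, median,
#'   matches), `n_matching`, `n_conditions`, `p.value`.
#' @export
gene_set_sign_test <- function(gene_z, gene_set, group_a,
                               group_b = character()) {
  stopifnot(length(gene_set) > 0, length(intersect(group_a, group_b)) == 0)
  m <- as_gene_matrix(gene_z, "z")
  m <- m[rownames(m) %in% gene_set, , drop = FALSE]
  conds <- c(group_a, group_b)
  missing_cond <- setdiff(conds, colnames(m))
  if (length(missing_cond) > 0) {
    stop("condition(s) absent from the z matrix: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  med <- apply(m[, conds, drop = FALSE], 2, stats::median, na.rm = TRUE)
  if (all(!is.finite(med))) stop("all medians are missing", call. = FALSE)
  group <- rep(c("A", "B"), c(length(group_a), length(group_b)))
  matches <- ifelse(group == "A", med < 0, med > 0)
  n <- sum(is.finite(med))
  k <- sum(matches, na.rm = TRUE)
  p <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(
    medians = tibble::tibble(condition = conds, group = group,
                             median = unname(med),
                             matches = unname(matches)),
    n_matching = k, n_conditions = n, p.value = p
  )
}

#' Similarity between environmental and genetic perturbation profiles
#'
#' Compares condition sensitivity profiles to external perturbation
#' profiles (e.g. genetic-interaction query profiles) over the shared gene
#' universe. Both matrices are independently normalized by alternating
#' row/column scaling for a fixed number of passes so every row and column
#' vector has Euclidean length approximately 1 (missing values are set to
#' 0 first); the similarity is then the inner product, and the top decile
#' of queries per condition is returned for downstream enrichment.
#'
#' @param env_profiles Conditions-by-genes numeric matrix.
#' @param query_profiles Queries-by-genes numeric matrix.
#' @param passes Number of alternating normalization passes (default 10).
#' @param min_shared Minimum shared genes (default 100).
#' @param top_fraction Fraction of queries reported per condition
#'   (default 0.10).
#' @return List with `similarity` (conditions x queries) and `top_queries`
#'   (named list per condition).
#' @export
cross_profile_similarity <- function(env_profiles, query_profiles,
                                     passes = 10L, min_shared = 100L,
                                     top_fraction = 0.10) {
  shared <- intersect(colnames(env_profiles), colnames(query_profiles))
  if (length(shared) < min_shared) {
    stop("shared gene universe too small (", length(shared), " genes, need ",
         min_shared, ")", call. = FALSE)
  }
  a <- bidirectional_normalize(env_profiles[, shared, drop = FALSE], passes)
  b <- bidirectional_normalize(query_profiles[, shared, drop = FALSE],
                               passes)
  sim <- tcrossprod(a, b)
  k <- max(1L, ceiling(top_fraction * nrow(b)))
  top <- apply(sim, 1, function(x) {
    names(sort(x, decreasing = TRUE))[seq_len(k)]
  }, simplify = FALSE)
  list(similarity = sim, top_queries = top)
}

#' @rdname cross_profile_similarity
#' @param m Numeric matrix; missing values are zeroed before scaling.
#' @export
bidirectional_normalize <- function(m, passes = 10L) {
  m[!is.finite(m)] <- 0
  for (i in seq_len(passes)) {
    rn <- sqrt(rowSums(m^2))
    m <- m / ifelse(rn > 0, rn, 1)
    cn <- sqrt(colSums(m^2))
    m <- sweep(m, 2, ifelse(cn > 0, cn, 1), "/")
  }
  # finish on a row pass so both directions end within tolerance
  rn <- sqrt(rowSums(m^2))
  m / ifelse(rn > 0, rn, 1)
}

#' Growth rates and adjusted scores from a liquid confirmation assay
#'
#' `liquid_growth_rate()` scores an optical-density time series as the
#' maximum OD (saturation) divided by the time to saturation, where the
#' saturation instant is the first timestamp at which the OD reaches 95%
#' of its maximum. `liquid_adjusted_score()` then expresses each mutant's
#' rate relative to wild-type in the same condition and renormalizes by the
#' same ratio in the reference condition, so a score of 1 means no
#' condition-specific effect, mirroring the agar z-score's logic.
#'
#' @param time_h Numeric vector of times (hours).
#' @param od Optical densities (same length, non-negative).
#' @param saturation_frac Fraction of the maximum OD defining saturation.
#' @return `liquid_growth_rate()`: a single rate (OD units per hour).
#' @export
liquid_growth_rate <- function(time_h, od, saturation_frac = 0.95) {
  stopifnot(length(time_h) == length(od), all(od >= 0, na.rm = TRUE))
  keep <- is.finite(time_h) & is.finite(od)
  t <- time_h[keep]
  x <- od[keep]
  if (length(t) < 2 || max(x) <= 0) return(NA_real_)
  t_sat <- t[which(x >= saturation_frac * max(x))[1]]
  if (t_sat <= 0) return(NA_real_)
  max(x) / t_sat
}

#' @rdname liquid_growth_rate
#' @param mutant,wildtype Tibbles with columns `strain`, `condition`,
#'   `well`, `time_h`, `od` (wild-type `strain` ignored).
#' @param reference_condition Condition label used for the final
#'   renormalization.
#' @return `liquid_adjusted_score()`: tibble with `strain`, `condition`,
#'   `adjusted_score`.
#' @export
liquid_adjusted_score <- function(mutant, wildtype,
                                  reference_condition = "glucose:ammonium") {
  well_rates <- function(d) {
    d |>
      dplyr::group_by(.data$strain, .data$condition, .data$well) |>
      dplyr::summarise(rate = liquid_growth_rate(.data$time_h, .data$od),
                       .groups = "drop") |>
      dplyr::group_by(.data$strain, .data$condition) |>
      dplyr::summarise(rate = mean(.data$rate, na.rm = TRUE),
                       .groups = "drop")
  }
  mut <- well_rates(mutant)
  wt <- well_rates(wildtype) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(wt_rate = mean(.data$rate, na.rm = TRUE),
                     .groups = "drop")
  if (any(!is.finite(wt$wt_rate) | wt$wt_rate <= 0)) {
    stop("wild-type rate is zero or undefined in some condition",
         call. = FALSE)
  }
  d <- dplyr::left_join(mut, wt, by = "condition")
  d$ratio <- d$rate / d$wt_rate
  ref <- d[d$condition == reference_condition, c("strain", "ratio")]
  if (nrow(ref) == 0) {
    stop("reference condition '", reference_condition,
         "' absent from the assay", call. = FALSE)
  }
  names(ref)[2] <- "ref_ratio"
  d <- dplyr::left_join(d, ref, by = "strain")
  if (any(!is.finite(d$ref_ratio) | d$ref_ratio <= 0)) {
    stop("missing or zero reference-condition measurement for some strain",
         call. = FALSE)
  }
  d$adjusted_score <- d$ratio / d$ref_ratio
  d[, c("strain", "condition", "adjusted_score")]
}
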