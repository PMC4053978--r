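#' Binarize significant effects into the factorization target
#'
#' Turns gene-level z-scores into the binary gene-by-condition `Data`
#' matrix decomposed by [nmf_signatures()]: a cell is 1 where the gene is a
#' significant hit at the 20% FDR condition-specific threshold (slow
#' effects by default, the sensitivity reading). Glycerol columns are
#' dropped (no z-scores are called on glycerol), only the first
#' glucose:ammonium replicate column (`glucose:ammonium01`) is kept so the
#' source-composition columns stay linearly independent, and genes with no
#' significant effect anywhere (all-zero rows) are removed.
#'
#' @param gene_z Gene-level tibble from [gene_zscores()].
#' @param thresholds Threshold tibble from [bh_thresholds()].
#' @param fdr_level FDR level of the thresholds to use (default 0.20).
#' @param direction `"slow"` (default) or `"either"` to also count fast
#'   hits.
#' @return Integer matrix (genes x conditions) of 0/1 with dimnames.
#' @export
binarize_effects <- function(gene_z, thresholds, fdr_level = 0.20,
                             direction = c("slow", "either")) {
  direction <- match.arg(direction)
  pc <- parse_condition(gene_z$condition)
  keep <- pc$carbon != "glycerol" &
    (pc$replicate %in% c(0L, 1L)) # only glucose:ammonium01 among replicates
  gz <- gene_z[keep, ]
  dirs <- if (direction == "slow") "slow" else c("slow", "fast")
  hits <- call_hits(gz, thresholds, fdr_level = fdr_level)
  hits <- hits[hits$direction %in% dirs, ]
  conds <- sort(unique(gz$condition))
  genes <- sort(unique(gz$strain))
  m <- matrix(0L, length(genes), length(conds),
              dimnames = list(genes, conds))
  if (nrow(hits) > 0) {
    m[cbind(match(hits$strain, genes), match(hits$condition, conds))] <- 1L
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) == 0) {
    stop("no genes with significant effects; empty data matrix",
         call. = FALSE)
  }
  m
}

#' Source-composition coefficient matrix
#'
#' Builds the fixed binary `Coefficients` matrix relating conditions to
#' their component nutrient sources: one row per source (3 carbons --
#' glycerol pairings are excluded from the decomposition -- and 7
#' nitrogens), one column per condition, with a single 1 in the carbon row
#' and a single 1 in the nitrogen row of each column (e.g. the glucose:urea
#' column has a 1 in the glucose row and a 1 in the urea row).
#'
#' @param conditions Character vector of condition labels (column order is
#'   preserved).
#' @return Binary matrix (sources x conditions) with dimnames.
#' @export
build_coefficients <- function(conditions) {
  pc <- parse_condition(conditions)
  if (any(pc$carbon == "glycerol")) {
    stop("glycerol conditions are excluded from the decomposition",
         call. = FALSE)
  }
  sources <- c(setdiff(carbon_sources(), "glycerol"), nitrogen_sources())
  h <- matrix(0L, length(sources), length(conditions),
              dimnames = list(sources, conditions))
  h[cbind(match(pc$carbon, sources), seq_along(conditions))] <- 1L
  h[cbind(match(pc$nitrogen, sources), seq_along(conditions))] <- 1L
  if (qr(h)$rank < min(dim(h))) {
    dup <- duplicated(paste(pc$carbon, pc$nitrogen))
    if (any(dup)) {
      stop("duplicate condition columns break linear independence: ",
           paste(conditions[dup], collapse = ", "), call. = FALSE)
    }
  }
  h
}

#' Fixed-coefficient non-negative matrix factorization
#'
#' Decomposes the binary effect matrix `Data (genes x conditions)` as
#' `Signatures (genes x sources) x Coefficients (sources x conditions)`,
#' where the source-composition `Coefficients` matrix is held fixed at its
#' defined 0/1 values and only the non-negative `Signatures` matrix is
#' learned. `Signatures` is initialized uniformly at random in (0, 1) and
#' refined by the multiplicative update
#' `W <- W * (V H') / (W H H' + eps)` for a fixed number of iterations; the
#' Frobenius reconstruction error is recorded each iteration and is
#' non-increasing. Fixing the coefficients gives each signature column
#' equal weight and prevents over-fitting driven by the sparsity of the
#' data and the very different number of hits per column.
#'
#' @param data Binary (or non-negative) matrix from [binarize_effects()].
#' @param coefficients Fixed source-composition matrix; defaults to
#'   [build_coefficients()] on the data's columns.
#' @param iterations Number of multiplicative updates (default 20; in
#'   practice the fit converges in fewer than 10).
#' @param seed Seed for the random initialization (default 0).
#' @param eps Small constant guarding the update denominator.
#' @return An object of class `cn_nmf`: list with `signatures` (genes x
#'   sources), `coefficients`, `error` (tibble of per-iteration Frobenius
#'   error, iteration 0 = initialization), `iterations`, `seed`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
nmf_signatures <- function(data, coefficients = NULL, iterations = 20L,
                           seed = 0L, eps = 1e-9) {
  stopifnot(is.matrix(data), all(data >= 0), iterations >= 1)
  h <- if (is.null(coefficients)) build_coefficients(colnames(data)) else
    coefficients
  if (ncol(data) != ncol(h)) {
    stop("data and coefficients disagree on the number of conditions",
         call. = FALSE)
  }
  h_fixed <- h # never updated; compared by identity downstream
  v <- data * 1.0
  with_preserved_seed({
    set.seed(as.integer(seed))
    w <- matrix(stats::runif(nrow(v) * nrow(h)), nrow(v), nrow(h),
                dimnames = list(rownames(v), rownames(h)))
    hht <- h %*% t(h)
    vht <- v %*% t(h)
    err <- numeric(iterations + 1)
    err[1] <- norm(v - w %*% h, "F")
    for (i in seq_len(iterations)) {
      w <- w * vht / (w %*% hht + eps)
      err[i + 1] <- norm(v - w %*% h, "F")
    }
    stopifnot(identical(h, h_fixed), all(w >= 0))
    structure(list(signatures = w, coefficients = h, data = v,
                   error = tibble::tibble(iteration = 0:iterations,
                                          error = err),
                   iterations = as.integer(iterations),
                   seed = as.integer(seed)),
              class = "cn_nmf")
  })
}

#' Per-source signature membership
#'
#' A gene belongs to a source's signature when its signature value exceeds
#' the cutoff (0.4 in the published analysis), i.e. it is sensitive to that
#' carbon or nitrogen source regardless of the partner nutrient.
#'
#' @param decomposition A `cn_nmf` from [nmf_signatures()].
#' @param cutoff Membership cutoff on raw signature values (default 0.4).
#' @return Named list of character vectors, one per source.
#' @export
signature_members <- function(decomposition, cutoff = 0.4) {
  stopifnot(inherits(decomposition, "cn_nmf"))
  w <- decomposition$signatures
  lapply(stats::setNames(colnames(w), colnames(w)),
         function(s) sort(rownames(w)[w[, s] > cutoff]))
}

#' @export
print.cn_nmf <- function(x, ...) {
  cat("Fixed-coefficient NMF signature decomposition\n")
  cat("  genes:", nrow(x$signatures), " sources:", ncol(x$signatures),
      " conditions:", ncol(x$coefficients), "\n")
  cat("  final Frobenius error:",
      signif(x$error$error[nrow(x$error)], 4), "after", x$iterations,
      "iterations\n")
  invisible(x)
}

#' @method tidy cn_nmf
#' @export
tidy.cn_nmf <- function(x, ...) {
  w <- x$signatures
  tibble::tibble(
    gene = rep(rownames(w), times = ncol(w)),
    source = rep(colnames(w), each = nrow(w)),
    value = as.vector(w)
  )
}

#' @method glance cn_nmf
#' @export
glance.cn_nmf <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$signatures), n_sources = ncol(x$signatures),
    n_conditions = ncol(x$coefficients), iterations = x$iterations,
    final_error = x$error$error[nrow(x$error)], seed = x$seed
  )
}

#' @method autoplot cn_nmf
#' @export
autoplot.cn_nmf <- function(object, ...) {
  ggplot2::ggplot(object$error,
                  ggplot2::aes(x = .data$iteration, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "multiplicative update iteration",
                  y = "Frobenius reconstruction error") +
    ggplot2::theme_minimal()
}
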