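#' LOWESS-normalize one plate of rates against a target plate
#'
#' Removes the rate-dependent scale difference between a plate and a target
#' plate sharing its layout. The ratio target/plate is LOWESS-smoothed
#' (locally linear, one robustifying iteration, window = `frac` of the
#' jointly finite positions) against the plate's own rate, and each rate is
#' multiplied by the smoothed ratio evaluated at that rate. Identical plates
#' are a fixed point; a constant scale factor is recovered exactly up to
#' smoother tolerance. Zero rates are excluded from the ratio fit (the ratio
#' is undefined at 0) and pass through unchanged, as do missing positions.
#'
#' @param x Numeric vector of plate rates (positions aligned with `target`).
#' @param target Numeric vector of target rates, same length.
#' @param frac LOWESS window as a fraction of available data (default 0.5).
#' @param min_overlap Minimum jointly finite positive positions required.
#' @return Numeric vector of normalized rates, same length as `x`.
#' @export
lowess_normalize <- function(x, target, frac = 0.5, min_overlap = 10L) {
  stopifnot(length(x) == length(target), frac > 0, frac <= 1)
  joint <- is.finite(x) & is.finite(target) & x > 0
  if (sum(joint) < min_overlap) {
    stop("insufficient overlap between plate and target (",
         sum(joint), " jointly finite positive positions, need ",
         min_overlap, ")", call. = FALSE)
  }
  ratio <- target[joint] / x[joint]
  fit <- stats::lowess(x[joint], ratio, f = frac, iter = 1)
  if (any(!is.finite(fit$y))) {
    # the robustness pass divides by the residual MAD, which is 0 for an
    # exact fit; fall back to the plain pass
    fit <- stats::lowess(x[joint], ratio, f = frac, iter = 0)
  }
  out <- x
  eval_at <- is.finite(x) & x > 0
  f_hat <- if (length(unique(fit$x)) < 2) {
    # degenerate abscissa (e.g. an all-identical plate): constant ratio
    rep(mean(ratio), sum(eval_at))
  } else {
    stats::approx(fit$x, fit$y, xout = x[eval_at], rule = 2,
                  ties = mean)$y
  }
  out[eval_at] <- x[eval_at] * f_hat
  out
}

#' Build the glucose:ammonium reference from six replicate plate sets
#'
#' For each array plate the replicate with the fewest missing rates is held
#' out as the anchor; the other five are LOWESS-normalized to it and all six
#' are averaged positionwise into the reference plate. The positionwise
#' standard deviation of the six normalized replicates about the reference
#' gives the strain-wise SD used in the z-score denominator.
#'
#' @param ga_rates Rate tibble (see [complete_rates()]) restricted to the
#'   glucose:ammonium replicate condition instances; exactly six instances
#'   are required.
#' @param lowess_frac LOWESS window fraction (default 0.5).
#' @return A tibble with one row per array position: `plate`, `row`, `col`,
#'   `strain`, `is_wildtype`, `ga_ref` (reference rate), `strain_sd`;
#'   with an `anchors` attribute mapping each plate to its anchor replicate.
#' @export
build_reference <- function(ga_rates, lowess_frac = 0.5) {
  pairs <- unique(condition_pair(ga_rates$condition))
  if (!identical(pairs, "glucose:ammonium")) {
    stop("reference must be built from glucose:ammonium replicates only",
         call. = FALSE)
  }
  reps <- sort(unique(ga_rates$condition))
  if (length(reps) != 6L) {
    stop("exactly six glucose:ammonium replicates are required, got ",
         length(reps), call. = FALSE)
  }
  by_plate <- split(ga_rates, ga_rates$plate)
  anchors <- tibble::tibble(plate = integer(), anchor = character())
  out <- purrr::map(by_plate, function(pp) {
    pp <- dplyr::arrange(pp, .data$condition, .data$row, .data$col)
    mats <- purrr::map(reps, function(r) {
      sub <- pp[pp$condition == r, ]
      stats::setNames(sub$rate, paste(sub$row, sub$col))
    })
    pos <- names(mats[[1]])
    stopifnot(all(purrr::map_lgl(mats, ~ identical(names(.x), pos))))
    n_missing <- purrr::map_int(mats, ~ sum(!is.finite(.x)))
    a <- which.min(n_missing)
    anchors <<- dplyr::bind_rows(anchors,
                                 tibble::tibble(plate = pp$plate[1],
                                                anchor = reps[a]))
    normed <- purrr::imap(mats, function(m, i) {
      if (i == a) m else lowess_normalize(m, mats[[a]], frac = lowess_frac)
    })
    nm <- do.call(cbind, normed)
    ga_ref <- rowMeans(nm, na.rm = TRUE)
    ga_ref[!is.finite(ga_ref)] <- NA_real_
    strain_sd <- apply(nm, 1, stats::sd, na.rm = TRUE)
    base <- pp[pp$condition == reps[1],
               c("plate", "row", "col", "strain", "is_wildtype")]
    base$ga_ref <- unname(ga_ref)
    base$strain_sd <- unname(strain_sd)
    base
  })
  res <- dplyr::bind_rows(out)
  attr(res, "anchors") <- anchors
  res
}

#' Normalize experimental condition plates against the reference
#'
#' Every plate of every condition instance is LOWESS-normalized (see
#' [lowess_normalize()]) against the glucose:ammonium reference plate of the
#' same array plate, removing the wholesale growth-rate difference between
#' the condition and the reference so that residuals reflect strain-specific
#' deviation only.
#'
#' @param rates Completed rate tibble (see [complete_rates()]).
#' @param reference Reference tibble from [build_reference()].
#' @param lowess_frac LOWESS window fraction (default 0.5).
#' @return The rate tibble with an added `norm_rate` column.
#' @export
normalize_rates <- function(rates, reference, lowess_frac = 0.5) {
  missing_plates <- setdiff(unique(rates$plate), unique(reference$plate))
  if (length(missing_plates) > 0) {
    stop("no reference for plate(s): ",
         paste(missing_plates, collapse = ", "), call. = FALSE)
  }
  ref <- reference[, c("plate", "row", "col", "ga_ref")]
  joined <- dplyr::left_join(rates, ref, by = c("plate", "row", "col"))
  joined |>
    dplyr::group_by(.data$condition, .data$plate) |>
    dplyr::group_modify(function(d, key) {
      d$norm_rate <- if (all(!is.finite(d$rate))) {
        d$rate
      } else {
        lowess_normalize(d$rate, d$ga_ref, frac = lowess_frac)
      }
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-"ga_ref")
}

#' Spatial bias filter for a single plate
#'
#' Removes smooth spatial artifacts (edge effects, gradients in pinning or
#' nutrient depth) from a plate of rates. Extreme values (top and bottom 5%)
#' and missing positions are temporarily replaced by the plate mean, then
#' refined to their two-dimensional Gaussian-filtered value over a few
#' passes (so the smooth surface can follow genuine spatial structure into
#' the masked cells instead of being anchored to the mean there), and the
#' zero-mean residual of the Gaussian-smoothed plate is subtracted from the
#' input. Only the zero-mean residual is removed, so the plate mean is
#' preserved; originally missing positions stay missing.
#'
#' @param plate Numeric matrix of rates (rows x columns of the plate).
#' @param sigma Gaussian filter SD in grid units (default 2).
#' @param trim Fraction trimmed at each tail when masking extremes
#'   (default 0.05).
#' @param refine_passes Refinement passes for masked cells (default 3;
#'   further passes change little).
#' @return Matrix of the same shape with the spatial residual removed.
#' @export
spatial_smooth <- function(plate, sigma = 2, trim = 0.05,
                           refine_passes = 3L) {
  stopifnot(is.matrix(plate))
  fin <- is.finite(plate)
  if (!any(fin)) {
    warning("all-missing plate passed to spatial_smooth; returned unchanged")
    return(plate)
  }
  mu <- mean(plate[fin])
  qs <- stats::quantile(plate[fin], c(trim, 1 - trim), names = FALSE,
                        type = 7)
  extreme <- fin & (plate < qs[1] | plate > qs[2])
  masked <- !fin | extreme
  work <- plate
  work[masked] <- mu
  for (i in seq_len(refine_passes)) {
    s <- gaussian_filter(work, sigma)
    work[masked] <- s[masked]
  }
  s2 <- gaussian_filter(work, sigma)
  out <- plate - (s2 - mean(s2))
  out[!fin] <- NA_real_
  out
}

# separable 2-D Gaussian convolution, kernel truncated at 3*sigma,
# reflective boundary
gaussian_filter <- function(m, sigma, truncate = 3) {
  r <- max(1L, ceiling(truncate * sigma))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  smooth_1d <- function(mm) { # along rows of mm (i.e. over row index)
    n <- nrow(mm)
    idx <- seq.int(1L - r, n + r)
    # reflect indices about the boundaries (1 and n)
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    padded <- mm[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(mm))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[seq.int(j, j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(smooth_1d(t(smooth_1d(m))))
}

#' Apply the spatial filter across a rate table
#'
#' Runs [spatial_smooth()] on the normalized rates of every
#' (condition instance, plate) separately.
#'
#' @param normalized Tibble from [normalize_rates()].
#' @param sigma,trim Passed to [spatial_smooth()].
#' @return The input tibble with `norm_rate` replaced by its spatially
#'   filtered value.
#' @export
smooth_rates <- function(normalized, sigma = 2, trim = 0.05) {
  normalized |>
    dplyr::group_by(.data$condition, .data$plate) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$row, .data$col)
      n_rows <- max(d$row)
      n_cols <- max(d$col)
      stopifnot(nrow(d) == n_rows * n_cols)
      m <- matrix(d$norm_rate, n_rows, n_cols, byrow = TRUE)
      sm <- suppressWarnings(spatial_smooth(m, sigma = sigma, trim = trim))
      d$norm_rate <- as.vector(t(sm))
      d
    }) |>
    dplyr::ungroup()
}
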