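#' Growth rate of a single colony
#'
#' The growth rate is the slope of the ordinary least-squares linear fit of
#' colony area (pixels) against time (seconds). Colonies with fewer than two
#' finite observations get a missing rate; a negative fitted slope is defined
#' to be a growth rate of 0 (the colony did not grow). The intercept is
#' always fitted because pinned colonies start at a nonzero area.
#'
#' @param time_s Numeric vector of timestamps in seconds, strictly increasing.
#' @param area_px Numeric vector of colony areas in pixels (same length).
#' @return A single growth rate in pixels/second, or `NA_real_`.
#' @examples
#' fit_growth_rate(c(0, 18000, 36000, 86400), c(0, 50, 100, 240))
#' @export
fit_growth_rate <- function(time_s, area_px) {
  stopifnot(length(time_s) == length(area_px))
  keep <- is.finite(time_s) & is.finite(area_px)
  t <- time_s[keep]
  a <- area_px[keep]
  if (is.unsorted(t, strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (length(t) < 2) return(NA_real_)
  slope <- stats::cov(t, a) / stats::var(t)
  max(slope, 0)
}

#' Growth rates for every colony of a screen
#'
#' Applies [fit_growth_rate()] to each colony series of a colony table and
#' assembles the per-position rate table, one row per array position and
#' condition instance. Positions flagged `curated_zero` (manually judged
#' correctly plated but non-viable) are forced to rate 0 regardless of the
#' fit; positions with fewer than two usable scans are missing. Strains
#' placed at several positions keep their position identity here --- they are
#' only collapsed after normalization, at the z-score level.
#'
#' @param colonies Colony tibble (see [read_colony_table()]).
#' @return A tibble with columns `condition`, `plate`, `row`, `col`,
#'   `strain`, `is_wildtype`, `curated_zero`, `rate`.
#' @export
compute_growth_rates <- function(colonies) {
  stopifnot(all(c("plate", "row", "col", "strain", "condition", "time_s",
                  "area_px") %in% names(colonies)))
  if (!"curated_zero" %in% names(colonies)) colonies$curated_zero <- FALSE
  fin <- is.finite(colonies$time_s) & is.finite(colonies$area_px)
  colonies$t0 <- ifelse(fin, colonies$time_s, 0)
  colonies$a0 <- ifelse(fin, colonies$area_px, 0)
  colonies$fin <- fin
  d <- colonies |>
    dplyr::arrange(.data$condition, .data$plate, .data$row, .data$col,
                   .data$time_s) |>
    dplyr::group_by(.data$condition, .data$plate, .data$row, .data$col,
                    .data$strain)
  if (any(!dplyr::mutate(d, ok = is.na(dplyr::lag(.data$time_s)) |
                           .data$time_s > dplyr::lag(.data$time_s))$ok,
          na.rm = TRUE)) {
    stop("timestamps within a colony must be strictly increasing",
         call. = FALSE)
  }
  # closed-form OLS slope from group sums (equivalent to fit_growth_rate)
  rates <- d |>
    dplyr::summarise(
      curated_zero = any(.data$curated_zero),
      n = sum(.data$fin),
      st = sum(.data$t0),
      sa = sum(.data$a0),
      sta = sum(.data$t0 * .data$a0),
      stt = sum(.data$t0^2),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rate = ifelse(.data$n >= 2,
                    pmax((.data$n * .data$sta - .data$st * .data$sa) /
                           (.data$n * .data$stt - .data$st^2), 0),
                    NA_real_),
      rate = ifelse(.data$curated_zero, 0, .data$rate),
      is_wildtype = .data$strain == "WT"
    )
  dplyr::select(rates, "condition", "plate", "row", "col", "strain",
                "is_wildtype", "curated_zero", "rate")
}

#' Complete a rate table against a layout
#'
#' Colonies that produced no usable image series are absent from the colony
#' table; this fills them back in as missing rates so every plate has its
#' full complement of positions (needed for positionwise reference building
#' and spatial filtering).
#'
#' @param rates Rate tibble from [compute_growth_rates()].
#' @param layout Layout tibble from [design_layout()].
#' @return Rate tibble covering every `condition` x layout position, with
#'   `NA` rates at unobserved positions.
#' @export
complete_rates <- function(rates, layout) {
  conds <- unique(rates$condition)
  full <- tidyr::expand_grid(condition = conds,
                             layout[, c("plate", "row", "col", "strain",
                                        "is_wildtype")])
  out <- dplyr::left_join(
    full, rates[, c("condition", "plate", "row", "col", "curated_zero",
                    "rate")],
    by = c("condition", "plate", "row", "col")
  )
  mismatch <- dplyr::anti_join(
    rates[, c("condition", "plate", "row", "col")], full,
    by = c("condition", "plate", "row", "col")
  )
  if (nrow(mismatch) > 0) {
    stop("rate table has positions absent from the layout (e.g. plate ",
         mismatch$plate[1], " row ", mismatch$row[1], " col ",
         mismatch$col[1], ")", call. = FALSE)
  }
  out$curated_zero[is.na(out$curated_zero)] <- FALSE
  out
}
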