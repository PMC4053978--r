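#' Nutrient source vocabularies
#'
#' The screen covers every pairwise combination of four carbon sources and
#' seven nitrogen sources (28 conditions). `glucose:ammonium` is the unique
#' reference condition; it is screened as six replicate plate sets so that a
#' reference and a replicate-based null can be built from it.
#'
#' @return Character vector of valid carbon (resp. nitrogen) source names.
#' @export
carbon_sources <- function() {
  c("glucose", "galactose", "ribose", "glycerol")
}

#' @rdname carbon_sources
#' @export
nitrogen_sources <- function() {
  c("ammonium", "proline", "glutamate", "glutamine", "arginine", "urea",
    "allantoin")
}

#' The full carbon-by-nitrogen condition grid
#'
#' @param ga_replicates Number of glucose:ammonium replicate plate sets to
#'   expand (default 6, the screen design). All other conditions appear once
#'   with `replicate = 0`.
#' @return A tibble with columns `carbon`, `nitrogen`, `replicate` and
#'   `condition` (the serialized label), one row per condition instance:
#'   27 single-instance conditions plus `ga_replicates` glucose:ammonium
#'   instances.
#' @examples
#' condition_grid()
#' @export
condition_grid <- function(ga_replicates = 6L) {
  stopifnot(ga_replicates >= 1L)
  grid <- tidyr::expand_grid(carbon = carbon_sources(),
                             nitrogen = nitrogen_sources())
  is_ref <- grid$carbon == "glucose" & grid$nitrogen == "ammonium"
  single <- dplyr::mutate(grid[!is_ref, ], replicate = 0L)
  ga <- tibble::tibble(carbon = "glucose", nitrogen = "ammonium",
                       replicate = seq_len(ga_replicates))
  out <- dplyr::bind_rows(ga, single)
  out$condition <- condition_label(out$carbon, out$nitrogen, out$replicate)
  out
}

#' Serialize and parse condition labels
#'
#' Labels are `"carbon:nitrogen"` in lowercase, with a two-digit replicate
#' suffix for the glucose:ammonium replicate plate sets
#' (e.g. `"glucose:ammonium01"`). `replicate = 0` means a single-instance
#' condition and adds no suffix.
#'
#' @param carbon,nitrogen Source names (vectorized).
#' @param replicate Integer replicate tag, 0 for single-instance conditions.
#' @return `condition_label()`: character vector of labels.
#' @examples
#' condition_label("glucose", "proline")
#' condition_label("glucose", "ammonium", 1)
#' parse_condition(c("glucose:proline", "glucose:ammonium03"))
#' @export
condition_label <- function(carbon, nitrogen, replicate = 0L) {
  stopifnot(all(carbon %in% carbon_sources()),
            all(nitrogen %in% nitrogen_sources()))
  replicate <- as.integer(replicate)
  if (any(replicate > 0L & !(carbon == "glucose" & nitrogen == "ammonium"))) {
    stop("replicate tags are reserved for glucose:ammonium", call. = FALSE)
  }
  suffix <- ifelse(replicate > 0L, sprintf("%02d", replicate), "")
  paste0(carbon, ":", nitrogen, suffix)
}

#' @param label Character vector of condition labels.
#' @return `parse_condition()`: a tibble with columns `carbon`, `nitrogen`,
#'   `replicate`, one row per label.
#' @rdname condition_label
#' @export
parse_condition <- function(label) {
  m <- regmatches(label, regexec("^([a-z]+):([a-z]+?)([0-9]{2})?$", label))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("unparseable condition label(s): ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  }
  carbon <- vapply(m, `[`, "", 2L)
  nitrogen <- vapply(m, `[`, "", 3L)
  rep_str <- vapply(m, `[`, "", 4L)
  unknown <- !(carbon %in% carbon_sources()) | !(nitrogen %in% nitrogen_sources())
  if (any(unknown)) {
    stop("unknown condition label(s): ",
         paste(unique(label[unknown]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    carbon = carbon,
    nitrogen = nitrogen,
    replicate = ifelse(rep_str == "", 0L, as.integer(rep_str))
  )
}

#' Strip the replicate tag from condition labels
#'
#' Maps every condition instance to its `(carbon, nitrogen)` pair label, so
#' the six `glucose:ammonium` replicate instances all map to
#' `"glucose:ammonium"`.
#'
#' @inheritParams parse_condition
#' @return Character vector of pair labels.
#' @export
condition_pair <- function(label) {
  p <- parse_condition(label)
  paste0(p$carbon, ":", p$nitrogen)
}
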