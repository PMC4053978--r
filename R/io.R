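#' Read a colony-area time-course table
#'
#' The colony table is the raw input of the pipeline: one row per scan of one
#' colony, tab-separated with header columns `plate`, `row`, `col`, `strain`,
#' `carbon`, `nitrogen`, `replicate`, `time_s`, `area_px` and optionally
#' `curated_zero` (a manual flag marking a colony as correctly plated but
#' non-viable, which forces its downstream growth rate to 0).
#'
#' @param path Path to a TSV file.
#' @return A tibble with the columns above (plus `condition`, the serialized
#'   label), validated: coordinates 1-based, timestamps strictly increasing
#'   within each colony, areas non-negative.
#' @export
read_colony_table <- function(path) {
  required <- c("plate", "row", "col", "strain", "carbon", "nitrogen",
                "replicate", "time_s", "area_px")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("colony table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(tab)) + 1L # header is line 1
  num <- function(col) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- is.na(x) & !is.na(tab[[col]]) & tab[[col]] != "NA"
    if (any(bad)) {
      stop(sprintf("non-numeric '%s' value at line %d: '%s'", col,
                   line[bad][1], tab[[col]][bad][1]), call. = FALSE)
    }
    x
  }
  out <- tibble::tibble(
    plate = as.integer(num("plate")),
    row = as.integer(num("row")),
    col = as.integer(num("col")),
    strain = tab$strain,
    carbon = tab$carbon,
    nitrogen = tab$nitrogen,
    replicate = as.integer(num("replicate")),
    time_s = num("time_s"),
    area_px = num("area_px")
  )
  out$curated_zero <- if ("curated_zero" %in% names(tab)) {
    cz <- as.logical(tab$curated_zero) # accepts TRUE/FALSE, T/F, 0/1 strings
    if (all(is.na(cz))) cz <- as.logical(as.numeric(tab$curated_zero))
    ifelse(is.na(cz), FALSE, cz)
  } else {
    FALSE
  }
  dup <- duplicated(out[, c("plate", "row", "col", "carbon", "nitrogen",
                            "replicate", "time_s")])
  if (any(dup)) {
    stop(sprintf("duplicate (plate,row,col,time) record at line %d",
                 line[dup][1]), call. = FALSE)
  }
  if (any(out$area_px < 0, na.rm = TRUE)) {
    stop("negative colony area encountered", call. = FALSE)
  }
  out$condition <- condition_label(out$carbon, out$nitrogen, out$replicate)
  decreasing <- out |>
    dplyr::arrange(.data$condition, .data$plate, .data$row, .data$col,
                   .data$time_s) |>
    dplyr::group_by(.data$condition, .data$plate, .data$row, .data$col) |>
    dplyr::summarise(ok = !is.unsorted(.data$time_s, strictly = TRUE),
                     .groups = "drop")
  if (any(!decreasing$ok)) {
    stop("timestamps within a colony must be strictly increasing",
         call. = FALSE)
  }
  out
}

#' Write a colony table
#'
#' @param colonies Colony tibble as produced by [read_colony_table()] or
#'   [simulate_experiment()].
#' @inheritParams read_colony_table
#' @return `path`, invisibly.
#' @export
write_colony_table <- function(colonies, path) {
  cols <- c("plate", "row", "col", "strain", "carbon", "nitrogen",
            "replicate", "time_s", "area_px", "curated_zero")
  readr::write_tsv(colonies[, intersect(cols, names(colonies))], path,
                   progress = FALSE)
  invisible(path)
}

#' Read and write strain-by-condition matrices
#'
#' Rate and z-score matrices serialize as TSV with a first column `strain`
#' and one column per condition label; missing cells are the literal token
#' `NA`. `read_rate_matrix()` validates the condition labels; read-then-write
#' is the identity on finite values and on the missing-value mask.
#'
#' @param rates A tibble in long format with columns `strain`, `condition`,
#'   and a value column (`rate` by default).
#' @param path File path.
#' @param value Name of the value column.
#' @return `read_rate_matrix()` returns the long tibble; `write_rate_matrix()`
#'   returns `path` invisibly.
#' @export
write_rate_matrix <- function(rates, path, value = "rate") {
  stopifnot(all(c("strain", "condition", value) %in% names(rates)))
  wide <- tidyr::pivot_wider(rates[, c("strain", "condition", value)],
                             names_from = "condition",
                             values_from = dplyr::all_of(value))
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_rate_matrix
#' @export
read_rate_matrix <- function(path, value = "rate") {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(wide) == 0 || ncol(wide) < 2) {
    stop("empty matrix file: ", path, call. = FALSE)
  }
  names(wide)[1] <- "strain"
  parse_condition(setdiff(names(wide), "strain")) # validates labels
  long <- tidyr::pivot_longer(wide, -"strain", names_to = "condition",
                              values_to = value)
  long[[value]] <- as.numeric(long[[value]])
  long
}

#' Read a published supplementary table
#'
#' Accepts the generic layouts used for re-saved supplementary material:
#' `kind = "rates"` and `"zscores"` are strain-by-condition matrices
#' (see [read_rate_matrix()]); `kind = "thresholds"` is a long table with
#' columns `condition`, `direction` (`fast`/`slow`), `fdr_level`,
#' `z_threshold`; `kind = "gene_lists"` is a two-column `term`, `gene` table
#' returned as a named list of gene sets.
#'
#' @param path File path (TSV).
#' @param kind One of `"rates"`, `"zscores"`, `"thresholds"`, `"gene_lists"`.
#' @return A tibble (long matrix or threshold table) or a named list of
#'   character vectors for `kind = "gene_lists"`.
#' @export
read_supplementary_matrix <- function(path,
                                      kind = c("rates", "zscores",
                                               "thresholds", "gene_lists")) {
  kind <- match.arg(kind)
  if (kind %in% c("rates", "zscores")) {
    return(read_rate_matrix(path, value = if (kind == "rates") "rate" else "z"))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0) stop("empty supplementary file: ", path, call. = FALSE)
  if (kind == "thresholds") {
    req <- c("condition", "direction", "fdr_level", "z_threshold")
    if (!all(req %in% names(tab))) {
      stop("threshold table needs columns: ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    parse_condition(unique(tab$condition))
    stopifnot(all(tab$direction %in% c("fast", "slow")))
    return(tibble::as_tibble(tab[, req]))
  }
  # gene_lists: two-column term/gene membership
  if (ncol(tab) < 2) stop("gene-set file needs two columns", call. = FALSE)
  names(tab)[1:2] <- c("term", "gene")
  split(tab$gene, tab$term)
}

#' Read a two-column term-to-gene membership file
#'
#' GO/KEGG annotation inputs are plain TSV with columns `term` and `gene`.
#'
#' @param path File path.
#' @return Named list mapping each term to its character vector of genes.
#' @export
read_gene_sets <- function(path) {
  read_supplementary_matrix(path, kind = "gene_lists")
}
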