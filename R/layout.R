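#' Plate-array layout for the screen design
#'
#' Builds the strain layout used by the screen: an array of `n_plates`
#' 16 x 24 plates in which one entire plate carries the wild-type strain and
#' every other plate carries wild-type controls scattered across its rows and
#' columns, topped up so that the whole array holds exactly `n_wildtype`
#' wild-type positions (701 in the genome-wide design). Remaining positions
#' are filled with mutant strains; when there are more positions than unique
#' mutants, the earliest mutants are placed a second time so some strains
#' occupy multiple positions, as in the real array.
#'
#' @param n_plates Number of plates (default 16).
#' @param n_rows,n_cols Plate geometry (default 16 x 24, i.e. 384 format).
#' @param n_mutants Number of distinct mutant strains (default 4772).
#' @param n_wildtype Total wild-type positions across the array (default 701).
#' @return A tibble with columns `plate`, `row`, `col`, `strain`,
#'   `is_wildtype`; one row per array position (1-based coordinates).
#' @examples
#' layout <- design_layout()
#' sum(layout$is_wildtype) # 701
#' @export
design_layout <- function(n_plates = 16L, n_rows = 16L, n_cols = 24L,
                          n_mutants = 4772L, n_wildtype = 701L) {
  n_plates <- as.integer(n_plates)
  stopifnot(n_plates >= 2L, n_rows >= 2L, n_cols >= 2L, n_mutants >= 1L)
  n_pos <- n_plates * n_rows * n_cols
  if (n_wildtype <= n_rows * n_cols || n_wildtype >= n_pos) {
    stop("n_wildtype must exceed one plate and leave room for mutants",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(plate = seq_len(n_plates), row = seq_len(n_rows),
                             col = seq_len(n_cols))
  wt <- matrix(FALSE, n_plates, n_rows * n_cols)
  wt[1L, ] <- TRUE # the dedicated wild-type plate

  # scatter controls on two diagonals of every other plate: every row gets
  # one, then extra positions until the array-wide count is reached
  remaining <- n_wildtype - n_rows * n_cols
  per_plate <- remaining %/% (n_plates - 1L)
  extras <- remaining %% (n_plates - 1L)
  for (p in seq.int(2L, n_plates)) {
    k <- per_plate + as.integer(p - 1L <= extras)
    stopifnot(k < 2L * n_rows) # two diagonals give 2 * n_rows slots
    pos <- integer(0)
    i <- 0L
    while (length(pos) < k) {
      r <- (i %% n_rows) + 1L
      offset <- if (i < n_rows) p else p + n_cols %/% 2L
      cc <- ((r - 1L + offset) %% n_cols) + 1L
      pos <- union(pos, (r - 1L) * n_cols + cc)
      i <- i + 1L
    }
    wt[p, pos[seq_len(k)]] <- TRUE
  }
  is_wt <- as.vector(t(wt))
  stopifnot(sum(is_wt) == n_wildtype)

  n_mut_pos <- n_pos - n_wildtype
  ids <- sprintf("mut%04d", seq_len(n_mutants))
  fill <- rep_len(ids, n_mut_pos) # duplicates cycle from the start
  strain <- character(n_pos)
  strain[is_wt] <- "WT"
  strain[!is_wt] <- fill
  dplyr::mutate(grid, strain = strain, is_wildtype = is_wt)
}
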