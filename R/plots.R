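#' Heatmap of clustered sensitivity profiles
#'
#' Draws the gene-by-condition z-score matrix of a [cluster_conditions()]
#' result with rows and columns ordered by their dendrograms --- the
#' clustergram view in which conditions organize by carbon source.
#'
#' @param clustering Result of [cluster_conditions()].
#' @param limits Symmetric color limits on z (default `c(-5, 5)`; values
#'   are clamped).
#' @return A ggplot object.
#' @export
plot_condition_clustergram <- function(clustering, limits = c(-5, 5)) {
  m <- clustering$matrix
  m <- m[clustering$genes$order, clustering$conditions$order, drop = FALSE]
  d <- tibble::tibble(
    gene = factor(rep(rownames(m), times = ncol(m)),
                  levels = rownames(m)),
    condition = factor(rep(colnames(m), each = nrow(m)),
                       levels = colnames(m)),
    z = pmax(pmin(as.vector(m), limits[2]), limits[1])
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$gene,
                                  fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = limits) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Precision-recall curve plot
#'
#' @param pr Tibble from [precision_recall()].
#' @param max_rank Optional rank cutoff for the x axis.
#' @return A ggplot object showing precision against recall rank, with the
#'   co-annotation background rate as a dashed reference line.
#' @export
plot_precision_recall <- function(pr, max_rank = NULL) {
  if (!is.null(max_rank)) pr <- pr[pr$rank <= max_rank, ]
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$rank, y = .data$precision)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = pr$background[1], linetype = "dashed") +
    ggplot2::labs(x = "recall (gene pairs)", y = "precision") +
    ggplot2::theme_minimal()
}

#' Spatial view of one plate of rates
#'
#' @param rates Rate tibble (e.g. from [normalize_rates()]).
#' @param condition,plate Which plate to draw.
#' @param value Column to map to fill (default `"rate"`).
#' @return A ggplot object laid out like the physical plate.
#' @export
plot_plate <- function(rates, condition, plate, value = "rate") {
  d <- rates[rates$condition == condition & rates$plate == plate, ]
  if (nrow(d) == 0) stop("no such plate/condition", call. = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data[[value]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(condition, ", plate ", plate),
                  x = "column", y = "row") +
    ggplot2::theme_minimal()
}
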