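#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_path geom_line
#'   geom_smooth labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a PCoA ordination
#'
#' Scatter of samples on the first two principal coordinates, optionally
#' coloured by a metadata column.
#'
#' @param object `limnotraj_pcoa` object.
#' @param metadata Optional metadata tibble (joined on `sample_id`).
#' @param colour Name of the metadata column to colour by.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.limnotraj_pcoa <- function(object, metadata = NULL, colour = "lake",
                                    ...) {
  df <- object$coordinates
  if (!is.null(metadata)) df <- dplyr::left_join(df, metadata, by = "sample_id")
  pct <- round(100 * object$variance_fraction[1:2], 1)
  p <- ggplot(df, aes(x = .data$Axis1, y = .data$Axis2))
  p <- if (!is.null(metadata) && colour %in% names(df)) {
    p + geom_point(aes(colour = .data[[colour]]))
  } else {
    p + geom_point()
  }
  p + labs(x = paste0("PCoA 1 (", pct[1], "%)"),
           y = paste0("PCoA 2 (", pct[2], "%)")) +
    theme_minimal()
}

#' Plot MOTA trajectories
#'
#' Monthly centroid paths of each lake through the first two shared
#' ordination axes.
#'
#' @param object `limnotraj_trajectory` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.limnotraj_trajectory <- function(object, ...) {
  cen <- attr(object, "centroids")
  axes <- setdiff(names(cen), c("lake", "month_index"))[1:2]
  ggplot(cen, aes(x = .data[[axes[1]]], y = .data[[axes[2]]],
                  colour = .data$lake)) +
    geom_path(arrow = grid::arrow(length = grid::unit(2, "mm"))) +
    geom_point(size = 0.8) +
    labs(x = axes[1], y = axes[2]) +
    theme_minimal()
}

#' Plot a time-lag analysis
#'
#' Dissimilarity against elapsed days with the fitted linear and best
#' polynomial curves overlaid.
#'
#' @param pairs Lag-pair tibble from [build_lag_pairs()].
#' @param fits Optional `limnotraj_tla` object; refitted when missing.
#' @return A ggplot.
#' @export
plot_time_lag <- function(pairs, fits = NULL) {
  if (is.null(fits)) fits <- fit_lag_models(pairs)
  models <- attr(fits, "fits")
  response <- attr(fits, "response")
  grid_x <- seq(min(pairs$lag_days), max(pairs$lag_days), length.out = 200)
  best_deg <- fits$degree[fits$best][1]
  curves <- dplyr::bind_rows(
    tibble::tibble(lag_days = grid_x, model = "linear",
                   fit = stats::predict(models[[1]],
                                        newdata = data.frame(x = grid_x))),
    if (best_deg > 1) {
      tibble::tibble(lag_days = grid_x, model = paste0("degree ", best_deg),
                     fit = stats::predict(models[[which(fits$degree == best_deg)]],
                                          newdata = data.frame(x = grid_x)))
    }
  )
  ggplot(pairs, aes(x = .data$lag_days, y = .data[[response]])) +
    geom_point(alpha = 0.5) +
    geom_line(data = curves, aes(y = .data$fit, colour = .data$model)) +
    labs(x = "Elapsed days", y = response, colour = NULL) +
    theme_minimal()
}

#' Plot a co-occurrence network
#'
#' Simple force-directed layout with nodes coloured by trophic mode and edge
#' type by correlation sign. Isolated nodes are hidden, matching how such
#' networks are usually displayed.
#'
#' @param net `igraph` graph from [build_cooccurrence_network()].
#' @param seed Layout seed.
#' @return A ggplot.
#' @export
plot_network <- function(net, seed = 1) {
  g <- igraph::delete_vertices(net, igraph::degree(net) == 0)
  if (igraph::vcount(g) == 0) rlang::abort("Network has no connected nodes.")
  lay <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(x = lay[, 1], y = lay[, 2],
                          mode = igraph::V(g)$mode)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble::tibble(
    x = lay[el[, 1], 1], y = lay[el[, 1], 2],
    xend = lay[el[, 2], 1], yend = lay[el[, 2], 2],
    sign = igraph::E(g)$sign
  )
  ggplot(nodes, aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = edges,
                          aes(xend = .data$xend, yend = .data$yend,
                              linetype = .data$sign),
                          colour = "grey60") +
    geom_point(aes(colour = .data$mode), size = 2) +
    ggplot2::theme_void()
}
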