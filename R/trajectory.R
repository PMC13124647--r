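#' Number of ordination axes covering a variance threshold
#'
#' Smallest number of leading PCoA axes whose cumulative variance fraction
#' strictly exceeds `threshold`. When even all axes do not exceed it, all
#' axes are used with a warning.
#'
#' @param ord `limnotraj_pcoa` object or numeric vector of variance fractions.
#' @param threshold Cumulative variance to exceed (default 0.90).
#' @return Integer number of axes.
#' @export
select_axes <- function(ord, threshold = 0.90) {
  vf <- if (inherits(ord, "limnotraj_pcoa")) ord$variance_fraction else ord
  cum <- cumsum(vf)
  k <- which(cum > threshold)
  if (length(k) == 0) {
    rlang::warn("Cumulative variance never exceeds the threshold; using all axes.")
    return(length(vf))
  }
  min(k)
}

#' Monthly community centroids in ordination space
#'
#' Averages the ordination coordinates of a lake's water-column replicates
#' within each sampling month (however many replicates survived QC). The
#' ordination is computed once over all lakes jointly, so centroids of
#' different lakes live in the same space and their trajectory lengths are
#' comparable.
#'
#' @param ord `limnotraj_pcoa` object (or its `coordinates` tibble).
#' @param metadata Sample metadata tibble.
#' @param n_axes Number of leading axes to keep (e.g. from [select_axes()]).
#' @return Tibble `lake`, `month_index`, then one column per retained axis.
#' @export
monthly_centroids <- function(ord, metadata, n_axes = NULL) {
  coords <- if (inherits(ord, "limnotraj_pcoa")) ord$coordinates else ord
  axes <- grep("^Axis", names(coords), value = TRUE)
  if (!is.null(n_axes)) axes <- axes[seq_len(n_axes)]
  joined <- dplyr::inner_join(coords, metadata, by = "sample_id")
  if (nrow(joined) == 0) rlang::abort("No samples shared between ordination and metadata.")
  joined |>
    dplyr::group_by(.data$lake, .data$month_index) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(axes), mean), .groups = "drop") |>
    dplyr::arrange(.data$lake, .data$month_index)
}

#' Cumulative trajectory length per lake
#'
#' Sums Euclidean distances between consecutive available monthly centroids,
#' from `start_month` (inclusive) to the end of the campaign. A month with no
#' samples is bridged by a single segment between its neighbours. Lengths are
#' normalised to the shortest lake trajectory.
#'
#' @param centroids Tibble from [monthly_centroids()].
#' @param start_month First month index to include (default: earliest present).
#' @return Object of class `limnotraj_trajectory`: tibble `lake`, `n_months`,
#'   `total_length`, `normalized_length`, with the centroid table kept in
#'   `attr(, "centroids")`.
#' @export
trajectory_lengths <- function(centroids, start_month = NULL) {
  axes <- setdiff(names(centroids), c("lake", "month_index"))
  if (!is.null(start_month)) {
    centroids <- dplyr::filter(centroids, .data$month_index >= start_month)
  }
  res <- centroids |>
    dplyr::arrange(.data$lake, .data$month_index) |>
    dplyr::group_by(.data$lake) |>
    dplyr::summarise(
      n_months = dplyr::n(),
      total_length = {
        m <- as.matrix(dplyr::pick(dplyr::all_of(axes)))
        if (nrow(m) < 2) rlang::abort("Need at least two monthly centroids per lake.")
        sum(sqrt(rowSums((m[-1, , drop = FALSE] -
                            m[-nrow(m), , drop = FALSE])^2)))
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(normalized_length = .data$total_length / min(.data$total_length))
  attr(res, "centroids") <- centroids
  class(res) <- c("limnotraj_trajectory", class(res))
  res
}

#' Multivariate trajectory analysis of monthly community change
#'
#' End-to-end MOTA: Bray-Curtis dissimilarities over all samples, one shared
#' PCoA, selection of the minimum number of axes exceeding the variance
#' threshold, monthly replicate centroids per lake, and cumulative
#' centroid-to-centroid trajectory lengths.
#'
#' @param counts Rarefied count tibble.
#' @param metadata Sample metadata tibble.
#' @param threshold Cumulative variance threshold for axis selection.
#' @param start_month First month index of the trajectories.
#' @return `limnotraj_trajectory` tibble; the number of retained axes is in
#'   `attr(, "n_axes")`.
#' @export
mota <- function(counts, metadata, threshold = 0.90, start_month = NULL) {
  ord <- pcoa_ordination(bray_curtis(counts))
  k <- select_axes(ord, threshold)
  cen <- monthly_centroids(ord, metadata, n_axes = k)
  res <- trajectory_lengths(cen, start_month = start_month)
  attr(res, "n_axes") <- k
  res
}

#' Correlate trajectory lengths with mean chlorophyll-a
#'
#' Spearman rank correlation between per-lake total trajectory length and
#' campaign-mean Chl-a concentration.
#'
#' @param trajectories `limnotraj_trajectory` tibble.
#' @param chla_means Tibble `lake`, `mean_chla` (e.g. campaign means).
#' @return Tibble `rho`, `p_value`, `n`.
#' @export
correlate_lengths_with_chla <- function(trajectories, chla_means) {
  joined <- dplyr::inner_join(as_tibble(trajectories), chla_means, by = "lake")
  if (nrow(joined) < 4) {
    rlang::warn("Fewer than 4 lakes; the length-Chla correlation is fragile.")
  }
  spearman_test(joined$total_length, joined$mean_chla)
}
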