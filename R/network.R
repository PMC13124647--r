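#' Select a lake's core ASVs
#'
#' Core ASVs are those reaching at least `threshold` (default 1%) relative
#' abundance in at least one sample of the table, bounds inclusive. Call on a
#' count table restricted to a single lake.
#'
#' @param counts Count tibble (one lake's samples).
#' @param threshold Relative-abundance cutoff (default 0.01).
#' @return Character vector of core ASV ids.
#' @export
select_core_asvs <- function(counts, threshold = 0.01) {
  m <- counts_matrix(counts)
  rel <- m / rowSums(m)
  colnames(m)[apply(rel, 2, max) >= threshold]
}

#' Build a signed co-occurrence network
#'
#' Nodes are all supplied taxa (isolated nodes are retained, so component
#' counts include singletons); an edge joins two taxa when the absolute
#' correlation reaches `min_corr` (inclusive), weighted by the signed
#' correlation.
#'
#' @param corr Symmetric correlation matrix (e.g. from [sparcc()]).
#' @param modes Optional tibble `asv_id`, `mode` for node annotation.
#' @param abundances Optional tibble `asv_id`, `mean_rel_abund`.
#' @param min_corr Edge threshold on `|rho|` (default 0.6).
#' @return An `igraph` graph with vertex attributes `mode` and
#'   `mean_rel_abund`, and edge attributes `weight` (rho) and `sign`.
#' @export
build_cooccurrence_network <- function(corr, modes = NULL, abundances = NULL,
                                       min_corr = 0.6) {
  ids <- rownames(corr)
  if (is.null(ids)) rlang::abort("`corr` must carry taxon ids as dimnames.")
  adj <- corr
  adj[abs(adj) < min_corr] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$sign <- ifelse(igraph::E(g)$weight > 0, "positive", "negative")
  }
  mode <- rep("unassigned", length(ids))
  if (!is.null(modes)) {
    hit <- modes$mode[match(ids, modes$asv_id)]
    mode[!is.na(hit)] <- hit[!is.na(hit)]
  }
  igraph::V(g)$mode <- mode
  if (!is.null(abundances)) {
    igraph::V(g)$mean_rel_abund <-
      abundances$mean_rel_abund[match(ids, abundances$asv_id)]
  }
  g
}

#' Co-occurrence network metrics
#'
#' The per-lake summary metrics: node and component counts (singletons
#' included), edge counts and sign percentages, global transitivity on the
#' unweighted unsigned graph, greedy modularity on absolute edge weights,
#' share of nodes in the largest connected component, per-trophic-mode
#' percentages of connected (degree >= 1) nodes, and module statistics where
#' a module is a connected component with at least two nodes (module trophic
#' richness counts distinct assigned modes, ignoring unassigned nodes).
#' Edge-dependent metrics are `NA` on an edgeless graph.
#'
#' @param net `igraph` graph from [build_cooccurrence_network()].
#' @param lake Optional lake label for the output row.
#' @return One-row tibble of metrics.
#' @export
network_metrics <- function(net, lake = NA_character_) {
  n_nodes <- igraph::vcount(net)
  n_edges <- igraph::ecount(net)
  comp <- igraph::components(net)
  deg <- igraph::degree(net)
  connected <- deg > 0
  mode <- igraph::V(net)$mode %||% rep("unassigned", n_nodes)

  if (n_edges > 0) {
    w <- igraph::E(net)$weight
    pct_pos <- 100 * mean(w > 0)
    pct_neg <- 100 * mean(w < 0)
    clust <- igraph::transitivity(net, type = "global")
    if (is.nan(clust)) clust <- NA_real_
    gu <- net
    igraph::E(gu)$weight <- abs(w)
    modul <- igraph::modularity(igraph::cluster_fast_greedy(gu))
  } else {
    pct_pos <- pct_neg <- clust <- modul <- NA_real_
  }

  pct_mode <- function(m) {
    if (!any(connected)) return(NA_real_)
    100 * sum(mode[connected] == m) / sum(connected)
  }

  module_ids <- which(tabulate(comp$membership) >= 2)
  richness <- vapply(module_ids, function(cid) {
    md <- mode[comp$membership == cid]
    length(setdiff(unique(md), "unassigned"))
  }, numeric(1))
  n_modules <- length(module_ids)

  tibble::tibble(
    lake = lake,
    core_asvs = n_nodes,
    components = comp$no,
    modules = n_modules,
    edges = n_edges,
    pct_positive_edges = pct_pos,
    pct_negative_edges = pct_neg,
    clustering_coefficient = clust,
    modularity = modul,
    pct_lcc_nodes = 100 * max(comp$csize) / n_nodes,
    pct_connected_phototroph = pct_mode("phototroph"),
    pct_connected_mixotroph = pct_mode("mixotroph"),
    pct_connected_phagotroph = pct_mode("phagotroph"),
    pct_connected_parasite = pct_mode("parasite"),
    pct_modules_all_modes = if (n_modules > 0) 100 * mean(richness == 4)
                            else NA_real_,
    module_mean_trophic_richness = if (n_modules > 0) mean(richness)
                                   else NA_real_
  )
}

#' Per-lake core-ASV network metrics
#'
#' Convenience pipeline: for each lake, restrict the count table to that
#' lake's samples, select core ASVs, estimate SparCC correlations, build the
#' thresholded network and compute its metrics.
#'
#' @param counts Rarefied count tibble over all lakes.
#' @param metadata Sample metadata tibble.
#' @param modes Optional tibble `asv_id`, `mode`.
#' @param core_threshold Core-ASV relative-abundance cutoff (default 0.01).
#' @param min_corr Edge threshold (default 0.6).
#' @param seed Optional integer seed (offset per lake for independent streams).
#' @param ... Passed to [sparcc()].
#' @return Tibble with one [network_metrics()] row per lake.
#' @export
lake_network_metrics <- function(counts, metadata, modes = NULL,
                                 core_threshold = 0.01, min_corr = 0.6,
                                 seed = NULL, ...) {
  lakes <- sort(unique(metadata$lake))
  purrr::imap_dfr(rlang::set_names(lakes), function(lk, i) {
    ids <- metadata$sample_id[metadata$lake == lk]
    sub <- dplyr::filter(counts, .data$sample_id %in% ids)
    core <- select_core_asvs(sub, core_threshold)
    sub <- sub[, c("sample_id", core)]
    lake_seed <- if (is.null(seed)) NULL else seed + match(lk, lakes)
    rho <- sparcc(sub, seed = lake_seed, ...)
    rel <- counts_matrix(sub)
    rel <- rel / rowSums(rel)
    ab <- tibble::tibble(asv_id = colnames(rel), mean_rel_abund = colMeans(rel))
    net <- build_cooccurrence_network(rho, modes = modes, abundances = ab,
                                      min_corr = min_corr)
    network_metrics(net, lake = lk)
  })
}

#' Aggregate network metrics by trophic category
#'
#' Per-category (and overall) arithmetic mean and sample standard deviation
#' (n - 1 denominator) of each numeric metric across member lakes. The SD is
#' `NA` for a single-lake category.
#'
#' @param records Tibble of per-lake metrics (e.g. [network_metrics()] rows).
#' @param categories Tibble `lake`, `category`.
#' @return Long tibble `category`, `metric`, `n_lakes`, `mean`, `sd`, with an
#'   `"overall"` category covering all lakes.
#' @export
aggregate_metrics_by_category <- function(records, categories) {
  joined <- dplyr::inner_join(records, categories, by = "lake")
  if (nrow(joined) < nrow(records)) {
    rlang::abort("Every lake in `records` must be categorized.")
  }
  num_cols <- names(joined)[vapply(joined, is.numeric, logical(1))]
  long <- joined |>
    tidyr::pivot_longer(dplyr::all_of(num_cols), names_to = "metric",
                        values_to = "value")
  per_cat <- long |>
    dplyr::group_by(.data$category, .data$metric) |>
    dplyr::summarise(n_lakes = dplyr::n(), mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1, stats::sd(.data$value),
                                 NA_real_),
                     .groups = "drop")
  overall <- long |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(category = "overall", n_lakes = dplyr::n(),
                     mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  dplyr::bind_rows(per_cat, overall) |>
    dplyr::select(dplyr::all_of(c("category", "metric", "n_lakes", "mean", "sd")))
}
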