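toy_corr <- function() {
  # triangle A-B-C, pair D-E (negative), singletons F, G, H
  ids <- LETTERS[1:8]
  r <- diag(8)
  dimnames(r) <- list(ids, ids)
  r["A", "B"] <- r["B", "A"] <- 0.9
  r["A", "C"] <- r["C", "A"] <- 0.7
  r["B", "C"] <- r["C", "B"] <- 0.65
  r["D", "E"] <- r["E", "D"] <- -0.75
  r["F", "G"] <- r["G", "F"] <- 0.59  # below threshold
  r
}

test_that("core ASV selection applies the inclusive 1% rule", {
  m <- rbind(c(2, 1, 10, 187), c(0, 2, 5, 293))  # totals 200, 300
  cts <- make_counts(m, asv_ids = c("one_pct", "sub_pct", "five_pct", "big"))
  core <- select_core_asvs(cts)
  expect_true("one_pct" %in% core)    # exactly 1% in sample 1
  expect_false("sub_pct" %in% core)   # peaks at 0.67%
  expect_true("five_pct" %in% core)
  # monotone: raising the threshold never adds ASVs
  expect_true(all(select_core_asvs(cts, 0.05) %in% core))
})

test_that("edges require |rho| >= 0.6 inclusive and keep signs", {
  net <- build_cooccurrence_network(toy_corr())
  expect_equal(igraph::vcount(net), 8)
  expect_equal(igraph::ecount(net), 4)
  el <- igraph::as_edgelist(net)
  expect_false(any(el == "F" | el == "G"))  # 0.59 makes no edge
  # boundary: exactly 0.60 is an edge
  r <- diag(4); dimnames(r) <- list(letters[1:4], letters[1:4])
  r[1, 2] <- r[2, 1] <- 0.60
  expect_equal(igraph::ecount(build_cooccurrence_network(r)), 1)
  signs <- igraph::E(net)$sign
  expect_equal(sum(signs == "negative"), 1)
})

test_that("network metrics match hand-computed values on the toy graph", {
  modes <- tibble::tibble(
    asv_id = LETTERS[1:8],
    mode = c("phototroph", "phototroph", "mixotroph", "phagotroph",
             "parasite", "phototroph", "mixotroph", "parasite"))
  net <- build_cooccurrence_network(toy_corr(), modes = modes)
  mt <- network_metrics(net, lake = "toy")
  expect_equal(mt$components, 5)   # triangle + pair + 3 singletons
  expect_equal(mt$modules, 2)
  expect_equal(mt$pct_lcc_nodes, 100 * 3 / 8)
  expect_equal(mt$clustering_coefficient, 1)  # all length-2 paths closed
  expect_equal(mt$pct_positive_edges + mt$pct_negative_edges, 100)
  # connected nodes: A,B,C,D,E -> 2 phototroph, 1 mixo, 1 phago, 1 parasite
  expect_equal(mt$pct_connected_phototroph, 40)
  expect_equal(mt$pct_connected_mixotroph, 20)
  # module richness: triangle {photo, photo, mixo} = 2; pair {phago, para} = 2
  expect_equal(mt$module_mean_trophic_richness, 2)
  expect_equal(mt$pct_modules_all_modes, 0)

  # path graph has zero transitivity
  r <- diag(3); dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  r[1, 2] <- r[2, 1] <- 0.7; r[2, 3] <- r[3, 2] <- 0.7
  expect_equal(network_metrics(build_cooccurrence_network(r))$clustering_coefficient,
               0)
  # edgeless graph reports NA for edge-dependent metrics
  r0 <- diag(5)
  dimnames(r0) <- list(letters[1:5], letters[1:5])
  mt0 <- network_metrics(build_cooccurrence_network(r0))
  expect_true(is.na(mt0$pct_positive_edges))
  expect_equal(mt0$components, 5)
})

test_that("category aggregation reproduces published summary arithmetic", {
  rec <- tibble::tibble(lake = c("VSM", "JAB", "CER-L", "CSM", "VSS"),
                        core_asvs = c(128, 126, 137, 154, 188))
  cats <- tibble::tibble(lake = rec$lake,
                         category = c(rep("oligo_meso", 3),
                                      rep("eu_hyper", 2)))
  agg <- aggregate_metrics_by_category(rec, cats)
  om <- agg[agg$category == "oligo_meso" & agg$metric == "core_asvs", ]
  expect_equal(round(om$mean, 1), 130.3)
  expect_equal(round(om$sd, 2), 5.86)
  eh <- agg[agg$category == "eu_hyper" & agg$metric == "core_asvs", ]
  expect_equal(eh$mean, 171.0)
  expect_equal(round(eh$sd, 2), 24.04)
  # single-lake category -> NA sd
  agg1 <- aggregate_metrics_by_category(
    rec[1:2, ], tibble::tibble(lake = c("VSM", "JAB"),
                               category = c("a", "b")))
  expect_true(all(is.na(agg1$sd[agg1$category != "overall"])))
  expect_error(aggregate_metrics_by_category(
    rec, cats[1:3, ]), "categorized")
})

test_that("per-lake pipeline produces one metrics row per lake", {
  cfg <- synthetic_config(n_lakes = 2, n_months = 6, n_asvs = 60, depth = 800,
                          trophic_level = c(0.3, 0.7))
  sim <- generate_lake_series(cfg, seed = 12)
  mt <- suppressWarnings(
    lake_network_metrics(sim$counts, sim$metadata, seed = 5, n_resamples = 5))
  expect_equal(nrow(mt), 2)
  expect_equal(mt$lake, c("L01", "L02"))
  expect_true(all(mt$core_asvs > 0))
  expect_true(all(mt$components + -1 * mt$modules >= 0))
})
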