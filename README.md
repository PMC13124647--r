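# limnotraj

Temporal community analysis for monthly 18S rRNA amplicon surveys of lakes
spanning a eutrophication gradient — the situation of peri-urban lake
networks where neighbouring water bodies range from oligotrophic to
hypereutrophic and the question is how trophic status shapes microeukaryote
community dynamics over time.

The package takes an ASV count table (samples × ASVs), taxonomy, sample
metadata (lake, date, water-column replicate), chlorophyll-a measurements
and a class-to-trophic-mode map, and provides:

* **Pre-processing** — lineage filtering (prokaryotes, metazoans,
  organellar reads, unassigned), seeded rarefaction without replacement.
* **Trophic annotation** — Carlson trophic-state classification from Chl-a
  (oligotrophic < 2.6 µg/L, mesotrophic 2.6–7.3, eutrophic 7.3–56,
  hypereutrophic > 56), campaign-level lake categorisation, trophic-mode
  assignment at the class rank (phototroph / mixotroph / phagotroph /
  parasite).
* **Community statistics** — richness, Shannon diversity H = −Σ pᵢ ln pᵢ,
  Bray–Curtis dissimilarity BC = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ), PCoA, sequential-SS
  PERMANOVA (`lake`, `season`, `lake:season`), Spearman tests,
  environmental PCA with cos² loadings.
* **MOTA** (multivariate trajectory analysis) — cumulative Euclidean path
  length of monthly community centroids through one shared PCoA space
  (minimum axes exceeding 90% variance), and its correlation with mean
  Chl-a.
* **TLA** (time-lag analysis) — Bray–Curtis dissimilarity vs elapsed days
  per lake, polynomial degree 1–5 model competition by AIC, and a
  divergence verdict from the linear slope.
* **Co-occurrence networks** — per-lake core ASVs (≥ 1% in ≥ 1 sample),
  SparCC basis-correlation estimation from log-ratio variances, signed
  networks at |ρ| ≥ 0.6, the standard metric panel (components, edge signs,
  transitivity, modularity, largest-component share, trophic-mode
  composition of modules) and category-level mean ± SD aggregation.
* **A synthetic generator** — multi-lake compositional time series with
  known seasonal, gradient and drift structure, so the whole pipeline is
  testable end to end without any sequence download.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects have
`tidy()` / `glance()` methods and `autoplot()` / `plot_*()` ggplot2 helpers.

## Worked example

A nine-lake, 18-month campaign with a trophic gradient and community drift
proportional to trophic level:

```r
library(limnotraj)

tau <- seq(0.1, 0.9, length.out = 9)
cfg <- synthetic_config(n_asvs = 300, depth = 4000,
                        trophic_level = tau, sigma_drift = tau)
sim <- generate_lake_series(cfg, seed = 2024)

# trophic categorisation from chlorophyll-a
categorize_lakes(sim$chla)

# MOTA: shared PCoA, monthly centroids, cumulative trajectory lengths
tr <- mota(sim$counts, sim$metadata)
tr
#>   lake  n_months total_length normalized_length
#> 1 L01         18         4.97              1
#> 2 L02         18         5.40              1.09
#> 3 L03         18         5.46              1.10
#> 4 L04         18         5.53              1.11
#> 5 L05         18         5.91              1.19
#> 6 L06         18         5.93              1.19
#> 7 L07         18         6.19              1.25
#> 8 L08         18         6.56              1.32
#> 9 L09         18         7.06              1.42

cm <- monthly_mean_chla(sim$chla) |>
  dplyr::group_by(lake) |>
  dplyr::summarise(mean_chla = mean(mean_chla))
correlate_lengths_with_chla(tr, cm)
#>     rho    p_value     n
#> 1     1 0.00000551     9
```

Trajectory lengths increase monotonically along the gradient (normalised to
the shortest lake), and the Spearman correlation with campaign-mean Chl-a is
perfect — the planted drift gradient is recovered. Time-lag analysis on the
most eutrophic lake flags sustained divergence:

```r
d  <- bray_curtis(sim$counts)
lp <- build_lag_pairs(d, sim$metadata, "L09")
divergence_test(lp)
#>   lake     slope     p_value verdict
#> 1 L09   0.000424 0.000000269 diverging
```

(slope and p shown for the default campaign, seed 2024), while
oligo-mesotrophic lakes come out `stationary`: seasonal oscillation without
year-to-year divergence.

Per-lake co-occurrence networks and the category summary table:

```r
map   <- read_trophic_modes(system.file("extdata", "trophic_modes.tsv",
                                        package = "limnotraj"))
mt    <- lake_network_metrics(sim$counts, sim$metadata, seed = 1)
cats  <- categorize_lakes(sim$chla)[, c("lake", "category")]
aggregate_metrics_by_category(mt, cats)
```

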