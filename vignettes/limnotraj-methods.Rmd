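---
title: "Methods: temporal trajectories of lake microeukaryote communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal trajectories of lake microeukaryote communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limnotraj)
```

# Scope and data model

limnotraj analyses monthly 18S rRNA amplicon time series from a set of lakes
spanning a eutrophication gradient. The central object is an ASV count table
— a tibble with a `sample_id` column and one non-negative integer column per
amplicon sequence variant — accompanied by a taxonomy table (up to eight PR2
ranks, rank 4 = class), sample metadata (lake, date, water-column replicate
W1–W3, derived month index and season), chlorophyll-a measurements
(lake x month x replicate, µg/L) and a class-to-trophic-mode map. The package
assumes the upstream read processing (denoising, chimera removal, taxonomic
classification) has already produced the ASV table; everything downstream of
that table is in scope.

# Pre-processing

**Lineage filtering.** ASVs whose lineage carries an excluded keyword as a
rank label are removed; the default keyword list targets prokaryotes,
metazoans, organellar 18S copies, land plants and unassigned reads. Keywords
match whole rank labels case-insensitively — substring matching would
misfire (e.g. "Chloroplast" inside "Chloroplastida") — and an ASV with an
entirely empty lineage counts as unassigned.

**Rarefaction.** Counts are subsampled *without replacement* to a common
depth (the convention of the ecosystem this package follows), so rarefied
counts never exceed the originals and every surviving sample sums exactly to
the target depth. Samples below the depth are dropped and reported rather
than padded; the campaign design this mirrors removed a handful of
low-coverage samples. A fixed seed makes the draw bit-identical across runs.
One draw is used; rarefaction-averaging is out of scope.

# Trophic state and trophic modes

Chlorophyll-a concentrations are binned by the Carlson trophic state index
chlorophyll ranges: oligotrophic < 2.6 µg/L, mesotrophic [2.6, 7.3),
eutrophic [7.3, 56], hypereutrophic > 56. Lower bounds are inclusive so the
bins partition the axis; the source ranges are open only at the extremes.

Campaign-level lake categories operationalise a narrative grouping:
`eu_hyper` when at least four monthly mean concentrations are
hypereutrophic; otherwise `oligo_meso` when at least half the monthly states
are oligotrophic or mesotrophic *and* the campaign mean is below 7.3 µg/L;
otherwise `meso_eu`. The two free choices (the 50% share and the mean
cut-off) were fixed once so that stable series at the reported
oligo-mesotrophic lake means (3.35, 4.33, 5.18 µg/L) categorise as
`oligo_meso`, intermediate fluctuating series as `meso_eu`, and the
four-hypereutrophic-months rule dominates everything else.

Trophic modes (phototroph, mixotroph, phagotroph, parasite) are assigned at
the class rank — the lowest rank with reliable assignment for most ASVs.
Class-level assignment ignores within-class variability; no sub-class
override mechanism is provided. The bundled map
(`inst/extdata/trophic_modes.tsv`) is a curated starting point for common
freshwater microeukaryote classes and is meant to be edited, not trusted
blindly.

# Community statistics

Alpha diversity is ASV richness and Shannon diversity with the natural
logarithm. Beta diversity uses Bray-Curtis dissimilarities on rarefied
counts. Principal coordinates come from Gower double-centering of `-d²/2`:
axes with positive eigenvalues are retained, coordinates are eigenvectors
scaled by the square root of their eigenvalues, and variance fractions are
relative to the sum of positive eigenvalues. No Lingoes/Cailliez correction
is applied; negative eigenvalues (routine for Bray-Curtis) are simply
dropped, which is adequate because every downstream use either keeps many
axes (trajectory analysis) or only plots the leading two.

PERMANOVA uses sequential (Type-I) sums of squares with terms ordered
`lake`, `season`, `lake:season` and free row permutations, with
`p = (1 + #{F* ≥ F}) / (n_perm + 1)` and 999 permutations by default.
Whether the original analysis used sequential or marginal partitioning is
not documented; sequential is assumed, and with it the term R² values plus
the residual sum to one exactly. A permutation matrix can be supplied in
place of a count, which the validation suite uses to compare against
exhaustive enumeration at n = 6.

Spearman tests use mid-ranks for ties, with the exact null distribution for
small untied samples (n ≤ 10) and the t approximation otherwise. The
environmental PCA operates on centred, unit-variance variables and reports
per-variable cos² (squared variable-component correlations), which sum to
one across all components.

# Trajectory analysis (MOTA)

One PCoA is computed over *all* lakes' samples jointly, so per-lake
trajectories live in a shared space and their lengths are comparable. The
number of retained axes is the smallest k whose cumulative variance fraction
strictly exceeds 0.90. Monthly centroids average the coordinates of however
many water-column replicates survived QC. The trajectory length is the sum
of Euclidean distances between consecutive *available* monthly centroids —
a missing month contributes one bridging segment, which is the only reading
consistent with computing a 17-month trajectory over a campaign with one
unsampled month — and lengths are also reported normalised to the shortest
lake. Trajectory length is invariant to rotation and translation of the
ordination and unchanged by collinear intermediate centroids; both
invariances are tested.

# Time-lag analysis (TLA)

For each lake and each unordered pair of sampling dates, the dissimilarity
is the mean of all replicate-to-replicate Bray-Curtis values between the two
dates (up to 3 x 3) — replicate-level pairing is not documented in the
source analysis, and the cross-replicate mean is deterministic and robust.
Ordinary least squares fits of dissimilarity on elapsed days are compared
across polynomial degrees 1–5 by AIC in the Gaussian convention,
`n log(2π RSS / n) + n + 2 (p + 1)`, counting the variance parameter, so
rankings are well defined; a perfect fit is reported as `AIC = -Inf` and
wins. The source describes dissimilarities "normalised by elapsed days" yet
plots and regresses raw dissimilarity against interval; both quantities are
emitted (`dissimilarity` and `rate`), and fitting defaults to the raw
dissimilarity. The divergence verdict is based on the degree-1 slope with a
two-sided t test at 0.05: significantly positive = "diverging",
significantly negative = "converging", otherwise "stationary".

# Co-occurrence networks

Per lake, core ASVs are those reaching ≥ 1% relative abundance in at least
one of that lake's samples (inclusive). SparCC estimates basis correlations
from log-ratio variances: per Dirichlet posterior resample (counts + 1),
the matrix `t_ij = var(log x_i / x_j)` is formed, basis variances are
solved from the linear approximation, and the strongest pair above the
exclusion threshold is iteratively removed from the system (defaults: 20
resamples, threshold 0.1, 10 exclusion rounds — the algorithm's published
defaults; the source names only the method). Estimates are averaged over
resamples and clipped to [-1, 1]; a singular system after exclusions falls
back to the unexcluded solution with a warning.

Networks take an edge at |ρ| ≥ 0.6 (the minimum admissible correlation,
inclusive). All core ASVs remain as nodes, so component counts include
singletons — required for the published metric combinations (e.g. 82
components among 128 core ASVs with a 30% largest component). Metrics:
global transitivity on the unweighted unsigned graph; greedy modularity
maximisation on absolute edge weights; largest-component node share;
per-trophic-mode percentages over connected (degree ≥ 1) nodes; and module
statistics where a module is a component with ≥ 2 nodes and module trophic
richness counts distinct assigned modes. The exact clustering and modularity
definitions used by the original wrapper are not documented, so per-lake
values are not bit-reproducible; only the category aggregation arithmetic
(mean and n−1 SD per trophic category) is, and that arithmetic is what the
validation suite pins down.

# The synthetic generator

`synthetic_config()` describes a campaign; the defaults are the emulated
design: nine lakes, 18 monthly time points from June of year one, three
water-column replicates, sequencing depth 12,287 reads (the rarefaction
depth of the emulated survey), 300 ASVs (a desk-scale stand-in for the
survey's ~20k; size does not change any tested property), and a trophic
gradient whose implied campaign categories reproduce the emulated 3 / 4 / 2
grouping of oligo-mesotrophic, meso-eutrophic and eu-hypereutrophic lakes,
with drift active in the two hypereutrophic lakes.

Latent log-abundances combine four parts:

* a regional baseline per ASV, drawn *uniformly* — a geometric-series
  (Motomura) rank-abundance profile. A Gaussian baseline was tried first and
  rejected: its right tail makes community dominance a lottery across seeds,
  occasionally collapsing a high-gradient lake to near-monoculture (median
  richness ~16), which stalls Bray-Curtis movement entirely;
* a per-lake offset (`lake_effect_sd`, default 0.6) making lakes distinct,
  and a dominance factor γ(τ) = 1 + τ scaling baseline spread so communities
  become more uneven with trophic level while staying at realistic
  per-sample richness;
* a 12-month seasonal cosine per ASV with random phase and amplitude
  (mean `seasonal_amplitude`, default 1), so no artificial global synchrony;
* a per-ASV random walk with step SD `sigma_drift` (default 0.3 for lakes
  with τ ≥ 0.75, else 0), *reflected* into ±3 log-units. A single lake-level
  regime walk was considered and rejected on two grounds: added equally to
  every ASV it cancels under compositional closure, and any single-walk
  variant makes the drift contribution to trajectory length so variable
  across realisations that planted gradients become unrecoverable. Per-ASV
  walks average over ASVs, giving a drift displacement that grows smoothly
  with `sigma_drift`; the reflection prevents a long walk from inflating one
  ASV into total dominance.

Replicate counts are Dirichlet-multinomial around the monthly composition
(precision `overdispersion`, default 200, carrying water-column
heterogeneity). Chlorophyll-a is lognormal (noise SD 0.25) around a median
`0.8 · 200^τ` µg/L with a log-scale summer peak of amplitude 0.8 — spanning
~1 µg/L at the bottom of the gradient to >100 µg/L at the top, matching the
emulated range, and guaranteeing ≥ 4 hypereutrophic months for the top
lakes. `expected_ground_truth()` maps a config to its implied categories and
orderings deterministically from the noiseless medians.

What the generator does *not* emulate: mechanistic ecology (no predator-prey
or nutrient dynamics), taxonomic realism of lineages, replicate-specific
spatial structure beyond symmetric overdispersion, and missing-month
patterns (all months are sampled unless the user drops samples). Passing
recovery tests therefore show that the pipeline recovers planted seasonal,
gradient and drift structure at realistic scales of noise — not that any
particular real lake behaves like the generator.

# Validation design and problem sizes

The validation suite runs at sizes chosen to make each property sharp while
keeping the whole suite quick on a laptop:

* exact oracles (Bray-Curtis, Shannon, Spearman with ties, the AIC formula,
  PCoA metric embedding, exhaustive-permutation PERMANOVA) on random
  instances of n ≤ 12;
* PERMANOVA type-I calibration: 500 null datasets x 999 permutations
  (12 samples, two groups), rejection at 0.05 expected in [0.03, 0.07];
* SparCC: planted basis correlation 0.8 among 50 taxa at n = 100 samples and
  depth 12,287 with a core-ASV-like abundance spread (`mean_sd = 0.5`;
  planted taxa drawn ultra-rare would conflate counting noise with estimator
  error), recovered within ±0.15 in ≥ 90% of 20 runs; null tables produce
  < 1% of pairs at |ρ| ≥ 0.6;
* MOTA: five drift levels x 10 replicates with common random numbers within
  a replicate (each replicate compares the same community under scaled
  drift, a standard paired-simulation variance reduction), per-level mean
  lengths strictly monotone; plus a nine-lake τ-gradient with
  `sigma_drift = τ` where the trajectory-length vs chlorophyll Spearman ρ
  exceeds 0.8 in ≥ 90% of runs at default generator settings;
* TLA: verdicts on 100 seasonal (stationary) and 100 drifting lakes each
  ≥ 90% correct; polynomial (degree ≥ 2) beats linear by AIC on
  cosine-generated data in ≥ 90% of 100 runs.

# Known limitations

Per-lake network metric values depend on undocumented choices in the
original wrapper and are not expected to match published per-lake cells;
the aggregation arithmetic is. Published aggregates were computed from
unrounded inputs, so recomputing them from printed per-lake values can
differ by one unit in the last printed digit. PERMANOVA inference assumes
exchangeable rows; monthly samples are autocorrelated, so its p-values are
anti-conservative for strong temporal structure (the source analysis shares
this caveat). The TLA verdict uses OLS t tests without autocorrelation
correction, by design matching the method it reimplements. SparCC assumes
sparse true correlation structure; dense interaction networks bias basis
variances.
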