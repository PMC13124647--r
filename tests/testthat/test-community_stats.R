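test_that("richness and Shannon match direct evaluation of the formulas", {
  expect_equal(asv_richness(c(5, 0, 1)), 2)
  expect_equal(asv_richness(rep(0, 4)), 0)
  expect_equal(shannon_diversity(c(10, 10, 10, 10)), log(4))
  expect_equal(shannon_diversity(c(0, 9, 0)), 0)
  expect_equal(shannon_diversity(c(75, 25)), 0.5623, tolerance = 1e-4)
  expect_error(shannon_diversity(c(0, 0)), "all-zero")

  # table version agrees with the oracle on random tables
  cts <- random_counts(6, 10, seed = 21)
  ad <- alpha_diversity(cts)
  m <- as.matrix(cts[, -1])
  expect_equal(ad$shannon, apply(m, 1, oracle_shannon))
  expect_equal(ad$richness, unname(apply(m, 1, function(x) sum(x > 0))))
})

test_that("rarefied richness never exceeds unrarefied richness", {
  cts <- random_counts(5, 30, seed = 8, lambda = 8)
  r <- suppressMessages(rarefy_counts(cts, depth = 100, seed = 2))
  keep <- match(r$sample_id, cts$sample_id)
  before <- alpha_diversity(cts[keep, ])$richness
  after <- alpha_diversity(r)$richness
  expect_true(all(after <= before))
})

test_that("Bray-Curtis matches the formula and its invariants", {
  expect_equal(as.numeric(bray_curtis(make_counts(rbind(c(6, 2, 0),
                                                        c(2, 2, 4))))), 0.5)
  expect_equal(as.numeric(bray_curtis(make_counts(rbind(c(1, 0),
                                                        c(0, 1))))), 1)
  expect_equal(as.numeric(bray_curtis(make_counts(rbind(c(3, 4),
                                                        c(3, 4))))), 0)
  cts <- random_counts(8, 12, seed = 5)
  d <- bray_curtis(cts)
  m <- as.matrix(cts[, -1])
  dm <- as.matrix(d)
  for (j in 1:7) for (k in (j + 1):8) {
    expect_equal(dm[j, k], oracle_bray_curtis(m[j, ], m[k, ]))
  }
  expect_true(all(dm >= 0 & dm <= 1))
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 8))
  expect_error(bray_curtis(make_counts(rbind(c(0, 0), c(1, 2)))), "zero total")
})

test_that("PCoA embeds Euclidean distances exactly", {
  # two-point geometry
  d2 <- stats::as.dist(matrix(c(0, 0.8, 0.8, 0), 2))
  ord2 <- pcoa_ordination(d2)
  expect_equal(sort(abs(ord2$coordinates$Axis1)), c(0.4, 0.4))
  # three equidistant points: two equal eigenvalues, 50/50
  d3 <- stats::as.dist(matrix(1, 3, 3) - diag(3))
  ord3 <- pcoa_ordination(d3)
  expect_equal(ord3$variance_fraction, c(0.5, 0.5), tolerance = 1e-12)
  # metric-embedding oracle: random planar points
  pts <- withr::with_seed(13, matrix(rnorm(24), 12, 2))
  d <- stats::dist(pts)
  ord <- pcoa_ordination(d)
  rec <- stats::dist(as.matrix(ord$coordinates[, -1]))
  expect_equal(as.numeric(rec), as.numeric(d), tolerance = 1e-8)
  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA partitions variance and matches brute-force enumeration", {
  # two tight groups, distance 1 apart -> group explains everything
  pts <- rbind(matrix(0, 3, 2), matrix(1, 3, 2))
  d <- stats::dist(pts)
  attr(d, "Labels") <- paste0("s", 1:6)
  g <- factor(rep(c("a", "b"), each = 3))
  pm <- permanova(d, data.frame(g = g), ~ g, n_perm = 199, seed = 1)
  td <- tidy(pm)
  expect_equal(td$r_squared[td$term == "g"], 1, tolerance = 1e-9)
  expect_equal(sum(td$r_squared, na.rm = TRUE), 2, tolerance = 1e-9) # terms+resid+total

  # exhaustive enumeration oracle at n = 6
  cts <- random_counts(6, 20, seed = 11)
  d <- bray_curtis(cts)
  Dm <- as.matrix(d)
  perms <- all_perms(6)
  Fs <- apply(perms, 1, function(pp) oracle_permanova_F(Dm, g, pp))
  Fobs <- oracle_permanova_F(Dm, g)
  p_oracle <- mean(Fs >= Fobs - 1e-12)
  nonid <- perms[rowSums(perms == matrix(1:6, nrow(perms), 6,
                                         byrow = TRUE)) < 6, ]
  pm2 <- permanova(d, data.frame(g = g), ~ g, n_perm = nonid)
  td2 <- tidy(pm2)
  expect_equal(td2$p_value[1], p_oracle, tolerance = 1e-12)
  expect_equal(td2$statistic[1], Fobs, tolerance = 1e-9)

  # same seed, same p-values
  pm3 <- permanova(d, data.frame(g = g), ~ g, n_perm = 199, seed = 5)
  pm4 <- permanova(d, data.frame(g = g), ~ g, n_perm = 199, seed = 5)
  expect_identical(tidy(pm3)$p_value, tidy(pm4)$p_value)
})

test_that("R-squared over lake, season and interaction terms sums to one", {
  cfg <- synthetic_config(n_lakes = 3, n_months = 8, n_asvs = 60, depth = 800,
                          trophic_level = c(0.2, 0.5, 0.8))
  sim <- generate_lake_series(cfg, seed = 77)
  d <- bray_curtis(sim$counts)
  pm <- permanova(d, sim$metadata, ~ lake * season, n_perm = 99, seed = 3)
  td <- tidy(pm)
  expect_setequal(td$term,
                  c("lake", "season", "lake:season", "Residual", "Total"))
  r2 <- td$r_squared[td$term != "Total"]
  expect_equal(sum(r2), 1, tolerance = 1e-9)
})

test_that("Spearman handles ties via mid-ranks and flags degenerate input", {
  expect_equal(spearman_test(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman_test(1:8, -(1:8))$rho, -1)
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  expect_equal(spearman_test(x, y)$rho, oracle_spearman_rho(x, y),
               tolerance = 1e-12)
  expect_warning(out <- spearman_test(rep(1, 5), 1:5), "rank variance")
  expect_true(is.na(out$rho))
  expect_error(spearman_test(1:2, 1:2), "at least 3")
})

test_that("environmental PCA cos2 behaves as squared correlations", {
  # two perfectly correlated variables -> PC1 carries everything
  z <- withr::with_seed(4, rnorm(30))
  env <- tibble::tibble(a = z, b = 2 * z + 5)
  p <- env_pca(env)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)
  expect_equal(unname(p$cos2[, 1]), c(1, 1), tolerance = 1e-12)
  # cos2 rows sum to one over all components
  env2 <- tibble::as_tibble(withr::with_seed(6,
    matrix(rnorm(80), 20, 4, dimnames = list(NULL, letters[1:4]))))
  p2 <- env_pca(env2)
  expect_equal(unname(rowSums(p2$cos2)), rep(1, 4), tolerance = 1e-9)
  expect_error(env_pca(tibble::tibble(a = rep(1, 5), b = 1:5)), "Constant")
})
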