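#' Alpha diversity per sample
#'
#' ASV richness (number of ASVs with positive counts) and Shannon diversity
#' (natural log) for every sample of a count table.
#'
#' @param counts Count tibble.
#' @return Tibble `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(counts) {
  m <- counts_matrix(counts)
  if (any(rowSums(m) == 0)) {
    rlang::abort("Shannon diversity is undefined for all-zero samples.")
  }
  tibble::tibble(
    sample_id = rownames(m),
    richness = as.integer(vegan::specnumber(m)),
    shannon = as.numeric(vegan::diversity(m, index = "shannon"))
  )
}

#' @rdname alpha_diversity
#' @param x Non-negative count vector for a single sample.
#' @export
asv_richness <- function(x) {
  if (any(x < 0)) rlang::abort("Counts must be non-negative.")
  sum(x > 0)
}

#' @rdname alpha_diversity
#' @export
shannon_diversity <- function(x) {
  if (any(x < 0)) rlang::abort("Counts must be non-negative.")
  if (sum(x) == 0) rlang::abort("Shannon diversity is undefined for an all-zero sample.")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities between samples,
#' `sum(|x - y|) / sum(x + y)`, typically on rarefied counts.
#'
#' @param counts Count tibble; every sample must have a positive total.
#' @return A `dist` object labelled by sample id.
#' @export
bray_curtis <- function(counts) {
  m <- counts_matrix(counts)
  if (any(rowSums(m) == 0)) {
    rlang::abort("Bray-Curtis is undefined for samples with zero total reads.")
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinate analysis
#'
#' Metric embedding of a dissimilarity matrix: Gower double-centering of
#' `-d^2/2` followed by eigendecomposition. Axes with positive eigenvalues
#' are retained; coordinates are eigenvectors scaled by the square root of
#' their eigenvalue, and variance fractions are taken relative to the sum of
#' positive eigenvalues (no Lingoes/Cailliez correction).
#'
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @return An object of class `limnotraj_pcoa`: list with `coordinates`
#'   (tibble `sample_id`, `Axis1`, ...), `eigenvalues` (positive, descending)
#'   and `variance_fraction`.
#' @export
pcoa_ordination <- function(d) {
  if (is.matrix(d)) {
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-10))) {
      rlang::abort("Dissimilarity matrix must be symmetric.")
    }
    d <- stats::as.dist(d)
  }
  if (!inherits(d, "dist")) rlang::abort("`d` must be a dist or symmetric matrix.")
  n <- attr(d, "Size")
  if (n < 2) rlang::abort("PCoA needs at least two samples.")
  # non-Euclidean dissimilarities routinely yield some non-positive
  # eigenvalues; that is handled below, so cmdscale's note is muffled
  fit <- withCallingHandlers(
    stats::cmdscale(d, k = n - 1, eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues are > 0", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  eig <- fit$eig
  pos <- which(eig > max(abs(eig)) * 1e-9)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_along(pos))
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  structure(list(
    coordinates = tibble::as_tibble(coords) |>
      dplyr::mutate(sample_id = ids, .before = 1),
    eigenvalues = eig[pos],
    variance_fraction = eig[pos] / sum(eig[pos])
  ), class = "limnotraj_pcoa")
}

#' @export
print.limnotraj_pcoa <- function(x, ...) {
  cat("PCoA ordination:", nrow(x$coordinates), "samples,",
      length(x$eigenvalues), "positive axes\n")
  cat("First axes (% variance):",
      paste0(round(100 * utils::head(x$variance_fraction, 5), 2), "%",
             collapse = ", "), "\n")
  invisible(x)
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate ANOVA with sequential (Type-I) partitioning of
#' the dissimilarity-based sums of squares, fitted by [vegan::adonis2()]
#' with `by = "terms"`. The default model tests lake identity, season and
#' their interaction, in that order; significance comes from free row
#' permutations with `p = (1 + #{F* >= F}) / (n_perm + 1)`.
#'
#' @param d A `dist` object.
#' @param data Data frame of factors, rows aligned with the samples of `d`.
#' @param formula Right-hand-side model formula over columns of `data`.
#' @param n_perm Number of permutations (default 999), or a permutation
#'   matrix (one permutation per row) for exact enumeration.
#' @param seed Optional integer seed for the permutation stream.
#' @return An object of class `limnotraj_permanova`; see
#'   [tidy.limnotraj_permanova()].
#' @export
permanova <- function(d, data, formula = ~ lake * season, n_perm = 999,
                      seed = NULL) {
  if (!inherits(d, "dist")) rlang::abort("`d` must be a dist object.")
  if (nrow(data) != attr(d, "Size")) {
    rlang::abort("`data` rows must align with the samples of `d`.")
  }
  if (is.numeric(n_perm) && length(n_perm) == 1 && n_perm < 99) {
    rlang::abort("Use at least 99 permutations.")
  }
  full <- stats::as.formula(paste("d", paste(deparse(formula), collapse = "")))
  run <- function() {
    vegan::adonis2(full, data = data, permutations = n_perm, by = "terms")
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(table = res, n_perm = n_perm, formula = formula),
            class = "limnotraj_permanova")
}

#' @export
print.limnotraj_permanova <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Spearman rank correlation test
#'
#' Rank correlation with mid-ranks for ties. The p-value uses the exact
#' distribution for small untied samples (n <= 10) and the t approximation
#' otherwise, following [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Tibble `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("`x` and `y` must have equal length.")
  if (length(x) < 3) rlang::abort("Need at least 3 observations.")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    rlang::warn("Zero rank variance; Spearman rho is undefined.")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- !has_ties && length(x) <= 10
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' PCA of environmental parameters
#'
#' Principal component analysis on centred, unit-variance-scaled variables,
#' with the quality of representation of each variable on each component
#' expressed as cos2 (squared variable-component correlation). Each
#' variable's cos2 values sum to 1 over all components.
#'
#' @param env Data frame of numeric environmental variables (one row per
#'   sample). An optional `sample_id` column is carried through to scores.
#' @return Object of class `limnotraj_envpca`: `scores` tibble, `eigenvalues`,
#'   `variance_fraction` and a `cos2` matrix (variables x components).
#' @export
env_pca <- function(env) {
  ids <- if ("sample_id" %in% names(env)) env$sample_id else
    as.character(seq_len(nrow(env)))
  vars <- env[, setdiff(names(env), "sample_id"), drop = FALSE]
  if (ncol(vars) < 2) rlang::abort("Need at least two environmental parameters.")
  if (!all(vapply(vars, is.numeric, logical(1)))) {
    rlang::abort("Environmental parameters must be numeric.")
  }
  sds <- vapply(vars, stats::sd, numeric(1))
  if (any(sds == 0)) {
    rlang::abort(paste0("Constant column(s): ",
                        paste(names(vars)[sds == 0], collapse = ", ")))
  }
  fit <- stats::prcomp(vars, center = TRUE, scale. = TRUE)
  # correlation of variable with component = loading * component sd (scaled PCA)
  cors <- sweep(fit$rotation, 2, fit$sdev, `*`)
  cos2 <- cors^2
  eig <- fit$sdev^2
  scores <- tibble::as_tibble(fit$x) |>
    dplyr::mutate(sample_id = ids, .before = 1)
  structure(list(scores = scores, eigenvalues = eig,
                 variance_fraction = eig / sum(eig), cos2 = cos2),
            class = "limnotraj_envpca")
}

#' @export
print.limnotraj_envpca <- function(x, ...) {
  cat("Environmental PCA:", nrow(x$cos2), "variables\n")
  cat("PC1/PC2 variance:",
      paste0(round(100 * x$variance_fraction[1:2], 1), "%", collapse = " / "),
      "\n")
  invisible(x)
}
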