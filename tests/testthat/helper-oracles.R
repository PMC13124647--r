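# Independent brute-force oracles and small fixture builders. These never
# call the package functions they are used to check.

oracle_bray_curtis <- function(x, y) {
  sum(abs(x - y)) / sum(x + y)
}

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

# mid-rank Pearson correlation
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Gaussian AIC, counting the variance parameter
oracle_aic <- function(rss, n, n_coef) {
  n * log(2 * pi * rss / n) + n + 2 * (n_coef + 1)
}

# Single-factor pseudo-F from a distance matrix via Gower centering and
# hat-matrix projection, for an arbitrary sample permutation of the labels.
oracle_permanova_F <- function(Dm, groups, perm = seq_along(groups)) {
  n <- nrow(Dm)
  J <- diag(n) - 1 / n
  G <- -0.5 * J %*% (Dm^2) %*% J
  X <- stats::model.matrix(~ groups[perm])
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  ssm <- sum(diag(H %*% G %*% H))
  ssr <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H)))
  df1 <- nlevels(groups) - 1
  df2 <- n - nlevels(groups)
  (ssm / df1) / (ssr / df2)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# count tibble from a plain matrix (samples x ASVs)
make_counts <- function(m, sample_ids = NULL, asv_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(m)))
  if (is.null(asv_ids)) asv_ids <- paste0("asv", seq_len(ncol(m)))
  dimnames(m) <- list(sample_ids, asv_ids)
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::mutate(out, sample_id = sample_ids, .before = 1)
}

random_counts <- function(n, p, seed, lambda = 20) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n * p, lambda), n, p)
    m[rowSums(m) == 0, 1] <- 1
    make_counts(m)
  })
}

# minimal 8-rank taxonomy row
make_taxonomy <- function(asv_id, class = NA_character_, rank2 = "Eukaryota2") {
  tibble::tibble(asv_id = asv_id, rank1 = "Eukaryota", rank2 = rank2,
                 rank3 = "Division", rank4 = class, rank5 = "Order",
                 rank6 = "Family", rank7 = "Genus", rank8 = "Species")
}
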