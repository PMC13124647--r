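#' SparCC compositional correlation estimation
#'
#' Estimates basis (absolute-abundance) correlations between taxa from
#' compositional count data using log-ratio variances. For each of
#' `n_resamples` posterior resamples, component fractions are drawn from a
#' Dirichlet with parameters `counts + 1`, the log-ratio variance matrix
#' `t_ij = var(log(x_i / x_j))` is computed, and the basis variances
#' `omega_i^2` are solved from the linear approximation
#' `sum_j t_ij = (m - 2) * omega_i^2 + sum_j omega_j^2` before converting to
#' correlations `rho_ij = (omega_i^2 + omega_j^2 - t_ij) / (2 omega_i omega_j)`.
#' The strongest-correlated pair above `exclusion_threshold` is iteratively
#' excluded from the system and the solution refreshed, for up to
#' `exclusion_iterations` rounds, so that a few strongly coupled taxa do not
#' bias the basis-variance estimates. The final estimate is the mean over
#' resamples, clipped to \[-1, 1\].
#'
#' Estimates are invariant (up to Monte-Carlo noise) to per-sample scaling of
#' the counts, which is the point of working on log-ratios.
#'
#' @param counts Count tibble restricted to the taxa of interest (e.g. a
#'   lake's core ASVs); at least 4 taxa, ideally >= 10 samples.
#' @param n_resamples Number of Dirichlet posterior resamples (default 20).
#' @param exclusion_threshold Correlation magnitude above which a pair may be
#'   excluded from the basis-variance system (default 0.1).
#' @param exclusion_iterations Maximum exclusion rounds per resample
#'   (default 10).
#' @param seed Optional integer seed.
#' @return Symmetric correlation matrix with unit diagonal, taxa as dimnames.
#' @export
sparcc <- function(counts, n_resamples = 20, exclusion_threshold = 0.1,
                   exclusion_iterations = 10, seed = NULL) {
  m <- counts_matrix(counts)
  if (ncol(m) < 4) rlang::abort("SparCC needs at least 4 taxa.")
  if (nrow(m) < 10) {
    rlang::warn("Fewer than 10 samples; SparCC estimates will be noisy.")
  }
  run <- function() {
    acc <- matrix(0, ncol(m), ncol(m))
    for (r in seq_len(n_resamples)) {
      frac <- rdirichlet_rows(m + 1)
      acc <- acc + sparcc_one(log(frac), exclusion_threshold,
                              exclusion_iterations)
    }
    acc / n_resamples
  }
  rho <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  rho <- pmin(pmax((rho + t(rho)) / 2, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(m), colnames(m))
  rho
}

# One SparCC pass on a log-fraction matrix (samples x taxa).
sparcc_one <- function(logf, exclusion_threshold, exclusion_iterations) {
  p <- ncol(logf)
  C <- stats::cov(logf)
  v <- diag(C)
  T_mat <- outer(v, v, `+`) - 2 * C     # t_ij = var(log x_i - log x_j)

  # linear system: M %*% omega^2 = rowSums of included t entries
  M <- matrix(1, p, p)
  diag(M) <- p - 1
  s <- rowSums(T_mat)
  base_rho <- NULL

  solve_rho <- function(M, s) {
    omega2 <- tryCatch(solve(M, s), error = function(e) NULL)
    if (is.null(omega2)) return(NULL)
    omega2 <- pmax(omega2, .Machine$double.eps)
    om <- sqrt(omega2)
    rho <- (outer(omega2, omega2, `+`) - T_mat) / (2 * outer(om, om))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    rho
  }

  rho <- solve_rho(M, s)
  if (is.null(rho)) rlang::abort("SparCC basis system is singular.")
  base_rho <- rho

  excluded <- matrix(FALSE, p, p)
  for (it in seq_len(exclusion_iterations)) {
    cand <- abs(rho)
    cand[excluded | row(cand) >= col(cand)] <- -Inf
    top <- which.max(cand)
    if (cand[top] <= exclusion_threshold) break
    i <- row(cand)[top]; j <- col(cand)[top]
    # excluding a pair whose taxa are nearly fully excluded destabilises the
    # system; stop instead
    if (M[i, i] <= 2 || M[j, j] <= 2) break
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    s[i] <- s[i] - T_mat[i, j]
    s[j] <- s[j] - T_mat[i, j]
    new_rho <- solve_rho(M, s)
    if (is.null(new_rho)) {
      rlang::warn("SparCC system singular after exclusions; using unexcluded solution.")
      return(base_rho)
    }
    rho <- new_rho
  }
  rho
}
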