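#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data %||% abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols across all_of n distinct pull
#'   rename row_number first
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats cor cor.test cov lm AIC coef pt rnorm runif rgamma
#'   rmultinom rlnorm cmdscale prcomp sd var setNames quantile median
#'   complete.cases dist
#' @importFrom utils head tail
NULL

# Convert a sample_id-keyed count tibble to an integer matrix (samples x ASVs).
counts_matrix <- function(counts) {
  check_count_tbl(counts)
  m <- as.matrix(counts[, setdiff(names(counts), "sample_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$sample_id
  m
}

# Inverse of counts_matrix().
as_count_tbl <- function(m) {
  tibble::as_tibble(m, .name_repair = "minimal") |>
    dplyr::mutate(sample_id = rownames(m), .before = 1)
}

# Validate the canonical ASV count-table shape.
check_count_tbl <- function(counts, call = rlang::caller_env()) {
  if (!is.data.frame(counts) || !"sample_id" %in% names(counts)) {
    rlang::abort("`counts` must be a data frame with a `sample_id` column.",
                 call = call)
  }
  asv_cols <- setdiff(names(counts), "sample_id")
  if (length(asv_cols) == 0) {
    rlang::abort("`counts` has no ASV columns.", call = call)
  }
  if (anyDuplicated(counts$sample_id)) {
    rlang::abort("Duplicate sample ids in `counts`.", call = call)
  }
  if (anyDuplicated(asv_cols)) {
    rlang::abort("Duplicate ASV ids in `counts`.", call = call)
  }
  vals <- as.matrix(counts[, asv_cols, drop = FALSE])
  if (!is.numeric(vals)) {
    rlang::abort("ASV counts must be numeric.", call = call)
  }
  if (anyNA(vals)) rlang::abort("ASV counts contain missing values.", call = call)
  if (any(vals < 0)) rlang::abort("ASV counts contain negative values.", call = call)
  if (any(vals != round(vals))) {
    rlang::abort("ASV counts must be integers.", call = call)
  }
  invisible(counts)
}

# Gaussian-convention AIC from a residual sum of squares; -Inf on a perfect fit.
rss_aic <- function(rss, n, n_coef, tss = NULL) {
  tol <- if (is.null(tss) || tss <= 0) 1e-12 else 1e-12 * tss
  if (rss <= tol) return(-Inf)
  n * log(2 * pi * rss / n) + n + 2 * (n_coef + 1)
}

# Meteorological season from a calendar month number.
month_season <- function(month) {
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "autumn", "autumn", "autumn", "winter")
  factor(s[month], levels = c("winter", "spring", "summer", "autumn"))
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

# Fold a random walk back into [-bound, bound] (reflecting boundaries):
# triangle-wave map with period 4*bound.
reflect_walk <- function(w, bound) {
  y <- (w + bound) %% (4 * bound)
  ifelse(y <= 2 * bound, y - bound, 3 * bound - y)
}

# One Dirichlet draw per row of a positive parameter matrix.
rdirichlet_rows <- function(alpha) {
  g <- matrix(stats::rgamma(length(alpha), shape = alpha, rate = 1),
              nrow = nrow(alpha))
  g / rowSums(g)
}
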