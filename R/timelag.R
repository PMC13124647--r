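#' Build date-to-date lag pairs for one lake
#'
#' For every unordered pair of sampling dates of a lake, the community
#' dissimilarity is the mean of all replicate-to-replicate Bray-Curtis values
#' between the two dates (up to 3 x 3), and the lag is the number of days
#' between the dates. A per-day rate column (`dissimilarity / lag_days`) is
#' also emitted; model fitting defaults to the raw dissimilarity.
#'
#' @param d `dist` of Bray-Curtis dissimilarities over all samples.
#' @param metadata Sample metadata tibble.
#' @param lake Lake identifier present in `metadata`.
#' @return Tibble `lake`, `date_a`, `date_b`, `lag_days`, `dissimilarity`,
#'   `rate`, with one row per unordered date pair (n(n-1)/2 rows).
#' @export
build_lag_pairs <- function(d, metadata, lake) {
  if (!lake %in% metadata$lake) {
    rlang::abort(paste0("Lake '", lake, "' absent from metadata."))
  }
  meta <- dplyr::filter(metadata, .data$lake == !!lake)
  dm <- as.matrix(d)
  meta <- dplyr::filter(meta, .data$sample_id %in% rownames(dm))
  dates <- sort(unique(meta$date))
  if (length(dates) < 3) rlang::abort("Need at least 3 sampling dates per lake.")
  pairs <- utils::combn(seq_along(dates), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    da <- dates[pairs[1, j]]; db <- dates[pairs[2, j]]
    sa <- meta$sample_id[meta$date == da]
    sb <- meta$sample_id[meta$date == db]
    tibble::tibble(
      lake = lake, date_a = da, date_b = db,
      lag_days = as.integer(db - da),
      dissimilarity = mean(dm[sa, sb])
    )
  })
  dplyr::mutate(out, rate = .data$dissimilarity / .data$lag_days)
}

#' Fit linear and polynomial time-lag models
#'
#' Ordinary least squares of dissimilarity on elapsed days for polynomial
#' degrees 1 through `max_degree`, ranked by AIC (Gaussian convention,
#' `n*log(2*pi*RSS/n) + n + 2*(p+1)`, counting the variance parameter). A
#' degree requiring more distinct lags than available is skipped with a
#' warning; a perfect fit (RSS ~ 0) is reported with `AIC = -Inf` and wins.
#'
#' @param pairs Lag-pair tibble from [build_lag_pairs()].
#' @param max_degree Highest polynomial degree (default 5).
#' @param response `"dissimilarity"` (default) or the per-day `"rate"`.
#' @return Object of class `limnotraj_tla`: tibble `degree`, `n`, `rss`,
#'   `aic`, `best`, plus `slope` and `slope_p` on the degree-1 row; fitted
#'   `lm` objects are kept in `attr(, "fits")`.
#' @export
fit_lag_models <- function(pairs, max_degree = 5,
                           response = c("dissimilarity", "rate")) {
  response <- match.arg(response)
  if (nrow(pairs) < 8) rlang::abort("Need at least 8 lag pairs to fit models.")
  y <- pairs[[response]]
  x <- pairs$lag_days
  n_distinct_lags <- dplyr::n_distinct(x)
  degrees <- seq_len(max_degree)
  feasible <- degrees[degrees <= n_distinct_lags - 1]
  if (length(feasible) < length(degrees)) {
    rlang::warn(paste0("Skipping degrees above ", max(feasible),
                       ": only ", n_distinct_lags, " distinct lags."))
  }
  tss <- sum((y - mean(y))^2)
  fits <- purrr::map(feasible, function(deg) {
    stats::lm(y ~ poly(x, deg, raw = TRUE))
  })
  rows <- purrr::map2_dfr(fits, feasible, function(fit, deg) {
    rss <- sum(stats::residuals(fit)^2)
    tibble::tibble(
      degree = deg, n = length(y), rss = rss,
      aic = rss_aic(rss, length(y), deg + 1, tss)
    )
  })
  lin <- summary(fits[[1]])$coefficients
  rows$slope <- NA_real_
  rows$slope_p <- NA_real_
  rows$slope[1] <- lin[2, "Estimate"]
  rows$slope_p[1] <- lin[2, "Pr(>|t|)"]
  rows$best <- rows$aic == min(rows$aic)
  attr(rows, "fits") <- fits
  attr(rows, "response") <- response
  class(rows) <- c("limnotraj_tla", class(rows))
  rows
}

#' Test for temporal divergence of a community
#'
#' Degree-1 time-lag regression with a two-sided t-test on the slope.
#' Verdict: `"diverging"` for a significantly positive slope (p < 0.05),
#' `"converging"` for a significantly negative one, `"stationary"` otherwise.
#'
#' @inheritParams fit_lag_models
#' @return Tibble `lake`, `slope`, `p_value`, `verdict`.
#' @export
divergence_test <- function(pairs, response = c("dissimilarity", "rate")) {
  response <- match.arg(response)
  y <- pairs[[response]]
  x <- pairs$lag_days
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  slope <- cf[2, "Estimate"]
  if (stats::var(y) == 0) {
    slope <- 0
    p <- 1
  } else {
    p <- cf[2, "Pr(>|t|)"]
  }
  verdict <- if (is.na(p) || p >= 0.05) "stationary"
             else if (slope > 0) "diverging" else "converging"
  tibble::tibble(lake = pairs$lake[1] %||% NA_character_,
                 slope = slope, p_value = p, verdict = verdict)
}
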