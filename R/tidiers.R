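#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PERMANOVA result
#'
#' @param x `limnotraj_permanova` object.
#' @param ... Unused.
#' @return Tibble `term`, `df`, `sum_sq`, `r_squared`, `statistic`, `p_value`.
#' @export
tidy.limnotraj_permanova <- function(x, ...) {
  tab <- as.data.frame(x$table)
  tibble::tibble(
    term = rownames(tab),
    df = tab$Df,
    sum_sq = tab$SumOfSqs,
    r_squared = tab$R2,
    statistic = tab$F,
    p_value = tab$`Pr(>F)`
  )
}

#' @rdname tidy.limnotraj_permanova
#' @return For `glance()`: one-row tibble with the total df, the number of
#'   permutations and the smallest term p-value.
#' @export
glance.limnotraj_permanova <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n = td$df[td$term == "Total"] + 1,
    n_perm = if (is.matrix(x$n_perm)) nrow(x$n_perm) else x$n_perm,
    min_p_value = suppressWarnings(min(td$p_value, na.rm = TRUE))
  )
}

#' Tidy a PCoA ordination
#'
#' @param x `limnotraj_pcoa` object.
#' @param ... Unused.
#' @return `tidy()`: the sample coordinates; `glance()`: one row per axis
#'   with eigenvalue and variance fraction.
#' @export
tidy.limnotraj_pcoa <- function(x, ...) x$coordinates

#' @rdname tidy.limnotraj_pcoa
#' @export
glance.limnotraj_pcoa <- function(x, ...) {
  tibble::tibble(
    axis = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$variance_fraction,
    cumulative_variance = cumsum(x$variance_fraction)
  )
}

#' Tidy time-lag model fits
#'
#' @param x `limnotraj_tla` object from [fit_lag_models()].
#' @param ... Unused.
#' @return `tidy()`: per-degree coefficients; `glance()`: per-degree RSS,
#'   AIC and best-model flag.
#' @export
tidy.limnotraj_tla <- function(x, ...) {
  fits <- attr(x, "fits")
  purrr::map2_dfr(fits, x$degree, function(fit, deg) {
    cf <- summary(fit)$coefficients
    tibble::tibble(degree = deg, term = rownames(cf),
                   estimate = cf[, "Estimate"],
                   std_error = cf[, "Std. Error"],
                   p_value = cf[, "Pr(>|t|)"])
  })
}

#' @rdname tidy.limnotraj_tla
#' @export
glance.limnotraj_tla <- function(x, ...) {
  tibble::as_tibble(x)[, c("degree", "n", "rss", "aic", "best")]
}

#' Tidy an environmental PCA
#'
#' @param x `limnotraj_envpca` object.
#' @param ... Unused.
#' @return `tidy()`: long tibble of per-variable cos2 on each component;
#'   `glance()`: per-component eigenvalue and variance fraction.
#' @export
tidy.limnotraj_envpca <- function(x, ...) {
  tibble::as_tibble(x$cos2, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "cos2")
}

#' @rdname tidy.limnotraj_envpca
#' @export
glance.limnotraj_envpca <- function(x, ...) {
  tibble::tibble(
    component = colnames(x$cos2),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$variance_fraction
  )
}
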