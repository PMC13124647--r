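#' Configuration for the synthetic lake-series generator
#'
#' Defines a multi-lake monthly amplicon campaign with known structure. The
#' defaults emulate the design the package targets: nine peri-urban lakes
#' sampled monthly for 18 months with three water-column replicates, a
#' eutrophication gradient (`trophic_level`, tau in \[0, 1\]) that controls
#' both expected chlorophyll-a and community dominance, per-ASV seasonal
#' cycles with a 12-month period, and a lake-level random-walk drift
#' component active in the hypereutrophic lakes.
#'
#' Chl-a medians follow `chla_base * chla_range^tau` with a log-scale summer
#' peak of amplitude `chla_seasonal_amp`; at the default settings the two
#' highest-tau lakes exceed the 56 ug/L hypereutrophic threshold during the
#' warm months, as the campaign this emulates observed.
#'
#' @param n_lakes,n_months,n_replicates Campaign dimensions.
#' @param n_asvs Number of ASVs.
#' @param depth Reads per replicate sample.
#' @param trophic_level Per-lake tau in \[0, 1\]; defaults to an even gradient.
#' @param seasonal_amplitude Mean per-ASV seasonal amplitude on the latent
#'   log scale.
#' @param sigma_drift Per-lake random-walk step SD; default 0.3 for lakes
#'   with tau >= 0.75, else 0.
#' @param dominance_gamma Function mapping tau to the latent baseline spread
#'   (higher spread = more uneven communities).
#' @param overdispersion Dirichlet-multinomial precision theta (replicate
#'   overdispersion; smaller = noisier replicates).
#' @param lake_effect_sd SD of the per-lake, per-ASV latent offset that makes
#'   lake communities distinct (default 0.6). Set small to isolate gradient
#'   effects in recovery experiments.
#' @param chla_base,chla_range,chla_seasonal_amp,chla_noise_sd Chl-a model:
#'   median scale, gradient range, log-scale seasonal amplitude, lognormal
#'   noise SD.
#' @param start_year,start_month_of_year Calendar anchor of month index 1.
#' @param correlated_pairs Optional tibble `asv_a`, `asv_b`, `rho` of planted
#'   basis correlations (used by [generate_correlated_counts()]).
#' @param seed Default seed carried by the config.
#' @return A `limnotraj_config` list.
#' @export
synthetic_config <- function(n_lakes = 9, n_months = 18, n_replicates = 3,
                             n_asvs = 300, depth = 12287,
                             trophic_level = NULL,
                             seasonal_amplitude = 1,
                             sigma_drift = NULL,
                             dominance_gamma = function(tau) 1 + tau,
                             overdispersion = 200,
                             lake_effect_sd = 0.6,
                             chla_base = 0.8, chla_range = 200,
                             chla_seasonal_amp = 0.8, chla_noise_sd = 0.25,
                             start_year = 2021, start_month_of_year = 6,
                             correlated_pairs = NULL, seed = NULL) {
  if (is.null(trophic_level)) {
    # default gradient; for nine lakes the implied campaign categories
    # reproduce the 3 oligo-meso / 4 meso-eu / 2 eu-hyper grouping of the
    # design this emulates
    trophic_level <- if (n_lakes == 9) {
      c(0.10, 0.20, 0.30, 0.42, 0.50, 0.55, 0.60, 0.80, 0.92)
    } else {
      seq(0.1, 0.9, length.out = n_lakes)
    }
  }
  if (length(trophic_level) != n_lakes) {
    rlang::abort("`trophic_level` must have one value per lake.")
  }
  if (is.null(sigma_drift)) {
    sigma_drift <- ifelse(trophic_level >= 0.75, 0.3, 0)
  }
  sigma_drift <- rep_len(sigma_drift, n_lakes)
  stopifnot(n_lakes >= 1, n_months >= 2, n_replicates >= 1, n_asvs >= 2,
            depth >= 1, all(sigma_drift >= 0), seasonal_amplitude >= 0,
            overdispersion > 0, chla_noise_sd >= 0)
  if (depth < n_asvs) {
    rlang::warn("Sequencing depth below the number of ASVs; tables will be sparse.")
  }
  structure(list(
    n_lakes = n_lakes, n_months = n_months, n_replicates = n_replicates,
    n_asvs = n_asvs, depth = depth,
    lakes = sprintf("L%02d", seq_len(n_lakes)),
    trophic_level = trophic_level,
    seasonal_amplitude = seasonal_amplitude,
    sigma_drift = sigma_drift,
    dominance_gamma = dominance_gamma,
    overdispersion = overdispersion,
    lake_effect_sd = lake_effect_sd,
    chla_base = chla_base, chla_range = chla_range,
    chla_seasonal_amp = chla_seasonal_amp, chla_noise_sd = chla_noise_sd,
    start_year = start_year, start_month_of_year = start_month_of_year,
    correlated_pairs = correlated_pairs, seed = seed
  ), class = "limnotraj_config")
}

# Calendar month (1..12) of month index t under a config.
cfg_calendar_month <- function(cfg, t) {
  ((cfg$start_month_of_year - 1 + t - 1) %% 12) + 1
}

# Noiseless monthly Chl-a median for lake l at month index t.
cfg_chla_median <- function(cfg, l, t) {
  m0 <- cfg$chla_base * cfg$chla_range^cfg$trophic_level[l]
  cal <- cfg_calendar_month(cfg, t)
  m0 * exp(cfg$chla_seasonal_amp * cos(2 * pi * (cal - 7) / 12))
}

#' Deterministic ground truth implied by a config
#'
#' Maps a generator configuration to the outcomes the pipeline should
#' recover: per-lake expected campaign category (from the noiseless monthly
#' Chl-a medians and the campaign categorisation rule), expected number of
#' hypereutrophic months, drift magnitudes (whose ranking the MOTA trajectory
#' lengths should reproduce), the seasonal period, and any planted
#' correlated pairs.
#'
#' @param cfg `limnotraj_config`.
#' @return A `limnotraj_truth` list with a per-lake tibble and scalars.
#' @export
expected_ground_truth <- function(cfg) {
  per_lake <- purrr::map_dfr(seq_len(cfg$n_lakes), function(l) {
    med <- vapply(seq_len(cfg$n_months), function(t) cfg_chla_median(cfg, l, t),
                  numeric(1))
    tibble::tibble(
      lake = cfg$lakes[l],
      trophic_level = cfg$trophic_level[l],
      sigma_drift = cfg$sigma_drift[l],
      expected_hyper_months = sum(classify_trophic_state(med) ==
                                    "hypereutrophic"),
      expected_category = categorize_lake(med)
    )
  })
  structure(list(per_lake = per_lake, seasonal_period = 12,
                 correlated_pairs = cfg$correlated_pairs),
            class = "limnotraj_truth")
}

#' Generate a synthetic multi-lake community time series
#'
#' Latent log-abundance of ASV i in lake l at month t:
#' `gamma(tau_l) * (baseline_i + lake_effect_il) +
#'  alpha_i * cos(2*pi*(t + phase_i)/12) + W_ilt`,
#' where `W_ilt` is a per-ASV random walk with step SD `sigma_drift[l]`
#' (independent across ASVs and lakes), reflected into \[-3, 3\] so that a
#' long walk keeps moving the composition without driving any single ASV to
#' total dominance. Drifting communities therefore follow a random walk in
#' composition space whose expected displacement grows smoothly with
#' `sigma_drift`. Replicate counts are Dirichlet-multinomial
#' around the monthly composition; Chl-a is lognormal around a tau- and
#' season-dependent median.
#'
#' @param cfg `limnotraj_config` from [synthetic_config()].
#' @param seed Integer seed (falls back to `cfg$seed`); same seed, same output.
#' @return A list of class `limnotraj_sim`: `counts` (tibble), `metadata`,
#'   `chla`, and `truth` (from [expected_ground_truth()]).
#' @export
generate_lake_series <- function(cfg, seed = cfg$seed) {
  if (is.null(seed)) rlang::abort("Provide a seed for a reproducible series.")
  withr::with_seed(seed, {
    asv_ids <- sprintf("ASV%04d", seq_len(cfg$n_asvs))
    # uniform log-abundance baseline = geometric-series (Motomura) rank
    # profile; bounded tails keep dominance controlled by gamma alone
    baseline <- stats::runif(cfg$n_asvs, -sqrt(3), sqrt(3))
    alpha <- cfg$seasonal_amplitude * stats::runif(cfg$n_asvs, 0, 2)
    phase <- stats::runif(cfg$n_asvs, 0, 12)

    counts_rows <- list()
    meta_rows <- list()
    chla_rows <- list()
    for (l in seq_len(cfg$n_lakes)) {
      lake <- cfg$lakes[l]
      gam <- cfg$dominance_gamma(cfg$trophic_level[l])
      lake_eff <- stats::runif(cfg$n_asvs, -sqrt(3) * cfg$lake_effect_sd,
                               sqrt(3) * cfg$lake_effect_sd)
      # per-ASV random walk (months x ASVs), reflected into [-3, 3] so drift
      # keeps moving the composition without single-ASV blow-up
      w <- apply(matrix(stats::rnorm(cfg$n_months * cfg$n_asvs,
                                     sd = cfg$sigma_drift[l]),
                        nrow = cfg$n_months), 2, cumsum)
      w <- reflect_walk(w, 3)
      for (t in seq_len(cfg$n_months)) {
        cal <- cfg_calendar_month(cfg, t)
        year <- cfg$start_year +
          (cfg$start_month_of_year - 1 + t - 1) %/% 12
        eta <- gam * (baseline + lake_eff) +
          alpha * cos(2 * pi * (t + phase) / 12) + w[t, ]
        p <- exp(eta - max(eta))
        p <- p / sum(p)
        med <- cfg_chla_median(cfg, l, t)
        for (r in seq_len(cfg$n_replicates)) {
          q <- rdirichlet_rows(matrix(cfg$overdispersion * p, nrow = 1))[1, ]
          cts <- as.integer(stats::rmultinom(1, cfg$depth, q))
          sid <- sprintf("%s_M%02d_W%d", lake, t, r)
          counts_rows[[sid]] <- cts
          meta_rows[[sid]] <- tibble::tibble(
            sample_id = sid, lake = lake,
            date = as.Date(sprintf("%d-%02d-01", year, cal)),
            month_index = t, replicate = paste0("W", r),
            season = month_season(cal)
          )
          chla_rows[[sid]] <- tibble::tibble(
            lake = lake, month_index = t, replicate = paste0("W", r),
            chla = stats::rlnorm(1, meanlog = log(med),
                                 sdlog = cfg$chla_noise_sd)
          )
        }
      }
    }
    cm <- do.call(rbind, counts_rows)
    colnames(cm) <- asv_ids
    structure(list(
      counts = as_count_tbl(cm),
      metadata = dplyr::bind_rows(meta_rows),
      chla = dplyr::bind_rows(chla_rows),
      truth = expected_ground_truth(cfg)
    ), class = "limnotraj_sim")
  })
}

#' Generate compositional counts with planted basis correlations
#'
#' Log-normal basis abundances with unit log-variance and the requested
#' correlations for planted taxon pairs (independent otherwise), closed to
#' fractions and sampled as multinomial counts — the standard validation
#' fixture for compositional correlation estimators.
#'
#' @param n_samples,n_asvs,depth Table dimensions and reads per sample.
#' @param pairs Optional tibble `asv_a`, `asv_b`, `rho` with taxon indices
#'   (1-based) and target basis correlations in (-1, 1).
#' @param seed Integer seed.
#' @param mean_sd SD of the per-taxon log-mean spread (default 1).
#' @return Count tibble; planted pairs are recorded in
#'   `attr(, "planted_pairs")`.
#' @export
generate_correlated_counts <- function(n_samples, n_asvs, depth, pairs = NULL,
                                       seed = NULL, mean_sd = 1) {
  if (is.null(seed)) rlang::abort("Provide a seed for a reproducible table.")
  if (!is.null(pairs)) {
    if (any(abs(pairs$rho) >= 1)) {
      rlang::abort("Target correlations must lie in (-1, 1).")
    }
  }
  sigma <- diag(n_asvs)
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$asv_a[k]; j <- pairs$asv_b[k]
      sigma[i, j] <- sigma[j, i] <- pairs$rho[k]
    }
  }
  ok <- tryCatch({chol(sigma); TRUE}, error = function(e) FALSE)
  if (!ok) rlang::abort("Planted covariance is not positive definite.")
  withr::with_seed(seed, {
    mu <- stats::rnorm(n_asvs, sd = mean_sd)
    logx <- MASS::mvrnorm(n_samples, mu = mu, Sigma = sigma)
    frac <- softmax_rows(logx)
    cm <- t(apply(frac, 1, function(q) stats::rmultinom(1, depth, q)[, 1]))
    colnames(cm) <- sprintf("ASV%04d", seq_len(n_asvs))
    rownames(cm) <- sprintf("S%04d", seq_len(n_samples))
    out <- as_count_tbl(cm)
    attr(out, "planted_pairs") <- pairs
    out
  })
}

#' @export
print.limnotraj_sim <- function(x, ...) {
  cat("Synthetic lake series:", nrow(x$counts), "samples,",
      ncol(x$counts) - 1, "ASVs,",
      dplyr::n_distinct(x$metadata$lake), "lakes\n")
  print(x$truth$per_lake)
  invisible(x)
}
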