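#' Trophic state and trophic mode levels
#'
#' `trophic_states()` returns the four Carlson chlorophyll-a states in
#' increasing order; `trophic_modes()` the four coarse ecological roles used
#' for class-rank annotation.
#'
#' @return Character vector of levels.
#' @export
trophic_states <- function() {
  c("oligotrophic", "mesotrophic", "eutrophic", "hypereutrophic")
}

#' @rdname trophic_states
#' @export
trophic_modes <- function() {
  c("phototroph", "mixotroph", "phagotroph", "parasite")
}

#' Classify trophic state from chlorophyll-a
#'
#' Bins concentrations using the Carlson trophic state index chlorophyll
#' ranges: oligotrophic below 2.6 ug/L, mesotrophic in \[2.6, 7.3),
#' eutrophic in \[7.3, 56\] and hypereutrophic above 56 ug/L. Lower bounds
#' are inclusive so the bins partition the non-negative axis.
#'
#' @param chla Numeric vector of concentrations (ug/L), >= 0.
#' @return Ordered factor over [trophic_states()].
#' @examples
#' classify_trophic_state(c(1.5, 2.6, 10, 374))
#' @export
classify_trophic_state <- function(chla) {
  if (anyNA(chla)) rlang::abort("Missing Chl-a concentrations.")
  if (any(chla < 0)) rlang::abort("Chl-a concentrations must be non-negative.")
  state <- ifelse(chla < 2.6, "oligotrophic",
           ifelse(chla < 7.3, "mesotrophic",
           ifelse(chla <= 56, "eutrophic", "hypereutrophic")))
  factor(state, levels = trophic_states(), ordered = TRUE)
}

#' Monthly mean chlorophyll-a per lake
#'
#' @param chla Chl-a tibble (`lake`, `month_index`, `replicate`, `chla`).
#' @return Tibble `lake`, `month_index`, `mean_chla`.
#' @export
monthly_mean_chla <- function(chla) {
  chla |>
    dplyr::group_by(.data$lake, .data$month_index) |>
    dplyr::summarise(mean_chla = mean(.data$chla), .groups = "drop")
}

#' Categorize a lake over a campaign
#'
#' Applies the campaign-level grouping rule to a series of monthly mean
#' Chl-a values: `eu_hyper` when at least four monthly states are
#' hypereutrophic; otherwise `oligo_meso` when at least half the monthly
#' states are oligotrophic or mesotrophic *and* the campaign mean is below
#' 7.3 ug/L; otherwise `meso_eu`.
#'
#' @param monthly_chla Numeric vector of monthly mean concentrations (ug/L).
#' @return One of `"oligo_meso"`, `"meso_eu"`, `"eu_hyper"`.
#' @export
categorize_lake <- function(monthly_chla) {
  if (length(monthly_chla) == 0) rlang::abort("Empty monthly Chl-a series.")
  if (length(monthly_chla) < 6) {
    rlang::warn("Fewer than 6 monthly values; campaign categorisation is unreliable.")
  }
  states <- classify_trophic_state(monthly_chla)
  if (sum(states == "hypereutrophic") >= 4) return("eu_hyper")
  low <- mean(states %in% c("oligotrophic", "mesotrophic"))
  if (low >= 0.5 && mean(monthly_chla) < 7.3) return("oligo_meso")
  "meso_eu"
}

#' Categorize every lake in a Chl-a table
#'
#' @param chla Chl-a tibble (`lake`, `month_index`, `replicate`, `chla`).
#' @return Tibble `lake`, `category`, `n_months`, `n_hyper_months`,
#'   `mean_chla`.
#' @export
categorize_lakes <- function(chla) {
  monthly_mean_chla(chla) |>
    dplyr::group_by(.data$lake) |>
    dplyr::summarise(
      category = categorize_lake(.data$mean_chla),
      n_months = dplyr::n(),
      n_hyper_months = sum(classify_trophic_state(.data$mean_chla) ==
                             "hypereutrophic"),
      mean_chla = mean(.data$mean_chla),
      .groups = "drop"
    )
}

#' Annotate ASVs with trophic modes at the class rank
#'
#' Looks up each ASV's 4th-rank (class) label in a class-to-mode map. ASVs
#' whose class is missing, empty or absent from the map receive
#' `"unassigned"`; this is a value, not an error, and the number of
#' unassigned ASVs is reported.
#'
#' @param taxonomy Taxonomy tibble from [read_taxonomy()].
#' @param mode_map Tibble `class`, `mode` from [read_trophic_modes()].
#' @return Tibble `asv_id`, `class`, `mode`.
#' @export
assign_trophic_modes <- function(taxonomy, mode_map) {
  cls <- if ("rank4" %in% names(taxonomy)) taxonomy$rank4 else
    rep(NA_character_, nrow(taxonomy))
  cls[is.na(cls) | !nzchar(cls)] <- NA_character_
  mode <- mode_map$mode[match(cls, mode_map$class)]
  mode[is.na(mode)] <- "unassigned"
  out <- tibble::tibble(asv_id = taxonomy$asv_id, class = cls, mode = mode)
  n_un <- sum(out$mode == "unassigned")
  if (n_un > 0) {
    rlang::inform(paste0(n_un, " of ", nrow(out),
                         " ASVs left unassigned by the trophic-mode map."))
  }
  out
}

#' Summarise trophic-mode shares of ASVs and reads
#'
#' Computes, per mode (including `"unassigned"`), the fraction of ASVs and
#' the fraction of total reads. Both columns sum to 1 across all categories.
#'
#' @param counts Count tibble.
#' @param modes Tibble `asv_id`, `mode` (e.g. from [assign_trophic_modes()]).
#' @return Tibble `mode`, `n_asvs`, `asv_fraction`, `reads`, `read_fraction`.
#' @export
summarize_modes <- function(counts, modes) {
  check_count_tbl(counts)
  m <- counts_matrix(counts)
  if (sum(m) == 0) rlang::abort("Count table holds no reads.")
  asv_ids <- colnames(m)
  mode <- modes$mode[match(asv_ids, modes$asv_id)]
  mode[is.na(mode)] <- "unassigned"
  lv <- c(trophic_modes(), "unassigned")
  reads <- colSums(m)
  tibble::tibble(mode = factor(mode, levels = lv), reads = reads) |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(n_asvs = dplyr::n(), reads = sum(.data$reads),
                     .groups = "drop") |>
    tidyr::complete(mode = factor(lv, levels = lv),
                    fill = list(n_asvs = 0L, reads = 0)) |>
    dplyr::mutate(asv_fraction = .data$n_asvs / sum(.data$n_asvs),
                  read_fraction = .data$reads / sum(.data$reads)) |>
    dplyr::select(dplyr::all_of(c("mode", "n_asvs", "asv_fraction",
                                  "reads", "read_fraction")))
}
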