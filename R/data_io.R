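#' Read an ASV count table
#'
#' Reads a tab-delimited table of non-negative integer read counts. In the
#' canonical orientation rows are samples (first column holds sample ids) and
#' columns are ASVs; set `samples_as_rows = FALSE` when the file stores ASVs
#' as rows, in which case the table is transposed on read.
#'
#' @param path Path to a TSV file.
#' @param samples_as_rows Logical; `TRUE` (default) when file rows are samples.
#' @return A tibble with a `sample_id` column followed by one integer column
#'   per ASV.
#' @export
read_asv_table <- function(path, samples_as_rows = TRUE) {
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       name_repair = "minimal", progress = FALSE)
  if (ncol(x) < 2) rlang::abort("Malformed header: count table needs id + count columns.")
  if (anyDuplicated(names(x))) {
    rlang::abort(paste0("Duplicate ", if (samples_as_rows) "ASV" else "sample",
                        " ids in header."))
  }
  for (j in seq(2, ncol(x))) {
    v <- suppressWarnings(as.numeric(x[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      rlang::abort(paste0("Malformed count table: non-numeric cell at data line ",
                          bad, ", column '", names(x)[j], "'."))
    }
    x[[j]] <- v
  }
  if (!samples_as_rows) {
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- x[[1]]
    x <- as_count_tbl(t(m))
  }
  names(x)[1] <- "sample_id"
  check_count_tbl(x)
  if (any(rowSums(counts_matrix(x)) == 0)) {
    rlang::abort("Count table contains samples with zero total reads.")
  }
  x
}

#' Write an ASV count table
#'
#' Writes the canonical dialect read by [read_asv_table()]: tab-delimited,
#' samples as rows, integer cells. `write_asv_table(read_asv_table(p), p2)`
#' round-trips byte-identically.
#'
#' @param counts Count tibble (`sample_id` + ASV columns).
#' @param path Output path.
#' @return `counts`, invisibly.
#' @export
write_asv_table <- function(counts, path) {
  check_count_tbl(counts)
  out <- counts
  asv_cols <- setdiff(names(out), "sample_id")
  out[asv_cols] <- lapply(out[asv_cols], as.integer)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(counts)
}

#' Read a taxonomy table
#'
#' Expects a TSV whose first column holds ASV ids followed by up to eight
#' rank columns in PR2 order (rank 4 is the class rank used for trophic-mode
#' annotation). Empty strings and `NA` are both treated as unassigned ranks.
#'
#' @param path Path to a TSV file.
#' @return A tibble with `asv_id` and rank columns renamed `rank1`..`rank8`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (ncol(x) < 2) rlang::abort("Taxonomy table needs an asv_id column plus ranks.")
  if (ncol(x) > 9) rlang::abort("Taxonomy table has more than 8 rank columns.")
  names(x) <- c("asv_id", paste0("rank", seq_len(ncol(x) - 1)))
  if (anyDuplicated(x$asv_id)) rlang::abort("Duplicate ASV ids in taxonomy table.")
  x
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `lake`, `date` (ISO-8601) and
#' `replicate` (one of W1/W2/W3). A `month_index` (1..N in chronological
#' order within the campaign) and a meteorological `season` are derived when
#' absent.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id`, `lake`, `date`, `month_index`,
#'   `replicate`, `season`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  need <- c("sample_id", "lake", "date", "replicate")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    rlang::abort(paste0("Metadata is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) rlang::abort("Unparseable (non ISO-8601) dates in metadata.")
  if (anyDuplicated(x[c("lake", "date", "replicate")])) {
    rlang::abort("Metadata rows must be unique on (lake, date, replicate).")
  }
  if (!"month_index" %in% names(x)) {
    months <- sort(unique(format(x$date, "%Y-%m")))
    x$month_index <- match(format(x$date, "%Y-%m"), months)
  } else {
    x$month_index <- as.integer(x$month_index)
  }
  if (!"season" %in% names(x)) {
    x$season <- month_season(as.integer(format(x$date, "%m")))
  } else {
    x$season <- factor(x$season, levels = c("winter", "spring", "summer", "autumn"))
  }
  dplyr::select(x, dplyr::all_of(c("sample_id", "lake", "date", "month_index",
                                   "replicate", "season")))
}

#' Read chlorophyll-a measurements
#'
#' Expects a CSV with columns `lake`, `month_index`, `replicate`, `chla`
#' (concentration in micrograms per litre).
#'
#' @param path Path to a CSV file.
#' @return A tibble with those four columns.
#' @export
read_chla <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  x <- readr::read_csv(path, col_types = readr::cols(
    lake = readr::col_character(),
    month_index = readr::col_integer(),
    replicate = readr::col_character(),
    chla = readr::col_double()
  ), progress = FALSE)
  if (anyNA(x$chla) || any(x$chla < 0)) {
    rlang::abort("Chl-a concentrations must be non-negative and non-missing.")
  }
  x
}

#' Read a trophic-mode map
#'
#' Two-column TSV `class<TAB>mode` mapping class-rank labels to one of the
#' four trophic modes. A curated starter map for common freshwater
#' microeukaryote classes ships with the package; see the example.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `class` and `mode`.
#' @examples
#' map <- read_trophic_modes(system.file("extdata", "trophic_modes.tsv",
#'                                       package = "limnotraj"))
#' @export
read_trophic_modes <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  names(x)[1:2] <- c("class", "mode")
  bad <- setdiff(unique(x$mode), trophic_modes())
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown trophic modes in map: ",
                        paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(x$class)) rlang::abort("Duplicate class labels in mode map.")
  x[c("class", "mode")]
}

#' Default lineage exclusion keywords
#'
#' Rank labels flagging non-target lineages in 18S surveys: prokaryotes,
#' metazoans, organellar sequences, land plants and unassigned reads.
#'
#' @return Character vector of keywords for [filter_lineages()].
#' @export
default_excluded_lineages <- function() {
  c("Bacteria", "Metazoa", "Mitochondria", "Chloroplast", "Streptophyta",
    "plastid", "nucleomorph", "unassigned")
}

#' Remove unwanted lineages from a count table
#'
#' Drops every ASV whose lineage carries one of the excluded keywords as a
#' rank label (matched case-insensitively at any rank). When `"unassigned"`
#' is among the keywords, ASVs with an entirely empty lineage — including
#' ASVs absent from the taxonomy table — are also dropped. Counts of
#' retained ASVs are untouched.
#'
#' @param counts Count tibble.
#' @param taxonomy Taxonomy tibble as returned by [read_taxonomy()].
#' @param exclude Character vector of keywords;
#'   defaults to [default_excluded_lineages()].
#' @return The filtered count tibble.
#' @export
filter_lineages <- function(counts, taxonomy,
                            exclude = default_excluded_lineages()) {
  check_count_tbl(counts)
  asv_ids <- setdiff(names(counts), "sample_id")
  if (length(exclude) == 0) return(counts)
  rank_cols <- grep("^rank", names(taxonomy), value = TRUE)
  lin <- as.matrix(taxonomy[, rank_cols, drop = FALSE])
  lin[is.na(lin)] <- ""
  rownames(lin) <- taxonomy$asv_id

  keywords <- tolower(exclude)
  drop_unassigned <- "unassigned" %in% keywords
  hit <- vapply(asv_ids, function(a) {
    if (!a %in% rownames(lin)) return(drop_unassigned)
    ranks <- tolower(lin[a, ])
    nonempty <- ranks[nzchar(ranks)]
    if (length(nonempty) == 0) return(drop_unassigned)
    any(nonempty %in% keywords)
  }, logical(1))

  keep <- asv_ids[!hit]
  if (length(keep) == 0) rlang::abort("No ASVs survive lineage filtering.")
  counts[, c("sample_id", keep)]
}

#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads. Samples whose total is below `depth` are dropped and reported (via
#' a message and the `"dropped_samples"` attribute); the study design this
#' mirrors removed low-depth samples rather than padding them.
#'
#' @param counts Count tibble.
#' @param depth Target depth (reads per sample), >= 1.
#' @param seed Optional integer seed; a fixed seed gives bit-identical output.
#' @return Rarefied count tibble whose row sums all equal `depth`, with the
#'   ids of dropped samples in `attr(, "dropped_samples")`.
#' @export
rarefy_counts <- function(counts, depth, seed = NULL) {
  check_count_tbl(counts)
  if (depth < 1) rlang::abort("`depth` must be >= 1.")
  m <- counts_matrix(counts)
  totals <- rowSums(m)
  dropped <- rownames(m)[totals < depth]
  if (length(dropped) == nrow(m)) {
    rlang::abort("All samples fall below the rarefaction depth.")
  }
  if (length(dropped) > 0) {
    rlang::inform(paste0("Dropping ", length(dropped),
                         " sample(s) below depth ", depth, ": ",
                         paste(dropped, collapse = ", ")))
    m <- m[!rownames(m) %in% dropped, , drop = FALSE]
  }
  draw <- function() vegan::rrarefy(m, depth)
  r <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- as_count_tbl(r)
  attr(out, "dropped_samples") <- dropped
  out
}
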