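test_that("ASV tables round-trip through the canonical TSV dialect", {
  cts <- random_counts(3, 2, seed = 1)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_asv_table(cts, p1)
  back <- read_asv_table(p1)
  expect_equal(dim(back), c(3, 3))
  expect_equal(counts_matrix <- as.matrix(back[, -1]), as.matrix(cts[, -1]),
               ignore_attr = TRUE)
  write_asv_table(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  # property over random tables
  for (s in 2:4) {
    cts <- random_counts(5, 7, seed = s)
    write_asv_table(cts, p1)
    expect_equal(as.matrix(read_asv_table(p1)[, -1]), as.matrix(cts[, -1]),
                 ignore_attr = TRUE)
  }
})

test_that("count validation rejects malformed tables", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ta\tb", "s1\t3\t-4", "s2\t1\t2"), p)
  expect_error(read_asv_table(p), "negative")
  writeLines(c("sample_id\ta\tb", "s1\t3\tx", "s2\t1\t2"), p)
  expect_error(read_asv_table(p), "non-numeric")
  writeLines(c("sample_id\ta\tb", "s1\t3\t4", "s1\t1\t2"), p)
  expect_error(read_asv_table(p), "Duplicate sample")
  writeLines(c("sample_id\ta\ta", "s1\t3\t4", "s2\t1\t2"), p)
  expect_error(read_asv_table(p), "Duplicate ASV")
  writeLines(c("sample_id\ta\tb", "s1\t0\t0", "s2\t1\t2"), p)
  expect_error(read_asv_table(p), "zero total")
})

test_that("transposed tables are accepted via the orientation flag", {
  cts <- random_counts(3, 4, seed = 9)
  m <- as.matrix(cts[, -1])
  rownames(m) <- cts$sample_id
  p <- withr::local_tempfile(fileext = ".tsv")
  tm <- t(m)
  readr::write_tsv(
    dplyr::mutate(tibble::as_tibble(tm), asv_id = rownames(tm), .before = 1), p)
  back <- read_asv_table(p, samples_as_rows = FALSE)
  expect_equal(as.matrix(back[, -1]), m, ignore_attr = TRUE)
  expect_equal(back$sample_id, cts$sample_id)
})

test_that("lineage filtering removes excluded groups and only those", {
  cts <- make_counts(matrix(1:8, 2, 4), asv_ids = paste0("asv", 1:4))
  tax <- dplyr::bind_rows(
    make_taxonomy("asv1", class = "Chlorophyceae"),
    make_taxonomy("asv2", class = "Cryptophyceae", rank2 = "Metazoa"),
    make_taxonomy("asv3", class = NA_character_) |>
      dplyr::mutate(dplyr::across(dplyr::starts_with("rank"), ~NA_character_)),
    make_taxonomy("asv4", class = "Spirotrichea")
  )
  out <- filter_lineages(cts, tax)
  expect_setequal(setdiff(names(out), "sample_id"), c("asv1", "asv4"))
  # counts of retained ASVs untouched
  expect_equal(out$asv1, cts$asv1)
  expect_equal(out$asv4, cts$asv4)
  # empty exclusion list = identity
  expect_equal(filter_lineages(cts, tax, exclude = character()), cts)
  # case-insensitive, and whole-rank matching avoids substring false hits
  out2 <- filter_lineages(cts, tax, exclude = "metazoa")
  expect_false("asv2" %in% names(out2))
  tax_chl <- make_taxonomy("asv1", class = "Chloroplastida")
  expect_true("asv1" %in%
    names(filter_lineages(cts[, c("sample_id", "asv1", "asv2")],
                          dplyr::bind_rows(tax_chl, make_taxonomy("asv2", "X")),
                          exclude = "Chloroplast")))
  # everything excluded -> explicit error
  expect_error(filter_lineages(cts, tax,
                               exclude = c("Eukaryota", "unassigned")),
               "survive")
})

test_that("ASVs missing from the taxonomy are treated as unassigned", {
  cts <- make_counts(matrix(1:4, 2, 2), asv_ids = c("asv1", "ghost"))
  tax <- make_taxonomy("asv1", class = "Chlorophyceae")
  out <- filter_lineages(cts, tax, exclude = "unassigned")
  expect_setequal(setdiff(names(out), "sample_id"), "asv1")
  out2 <- filter_lineages(cts, tax, exclude = "Metazoa")
  expect_true("ghost" %in% names(out2))
})

test_that("rarefaction conserves depth, drops shallow samples, reproduces", {
  m <- matrix(c(60, 40, 0,
                10, 5, 5,
                100, 200, 300), 3, 3, byrow = TRUE)
  cts <- make_counts(m)
  expect_message(r <- rarefy_counts(cts, depth = 50, seed = 7), "s2")
  expect_equal(attr(r, "dropped_samples"), "s2")
  expect_true(all(rowSums(as.matrix(r[, -1])) == 50))
  # per-ASV rarefied count never exceeds the original
  orig <- as.matrix(cts[cts$sample_id %in% r$sample_id, -1])
  expect_true(all(as.matrix(r[, -1]) <= orig))
  # full draw leaves counts unchanged
  full <- rarefy_counts(make_counts(matrix(c(5, 7), 1, 2)), depth = 12, seed = 1)
  expect_equal(as.numeric(as.matrix(full[, -1])), c(5, 7))
  # bit-identical under a fixed seed
  r2 <- suppressMessages(rarefy_counts(cts, depth = 50, seed = 7))
  expect_identical(r, r2)
  expect_error(rarefy_counts(cts, depth = 1e6), "below the rarefaction depth")
})
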