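make_raw <- function(n = 2) {
  data.frame(occurrence_no = seq_len(n), collection_no = 1,
             accepted_name = paste("Taxon sp", seq_len(n)),
             accepted_rank = "species",
             paleolng = seq(-170, 170, length.out = max(n, 2))[seq_len(n)],
             paleolat = 20,
             max_ma = 72, min_ma = 66, reference_no = 1, cc = "EU",
             environment = "terrestrial indet.", group_tags = "",
             stringsAsFactors = FALSE)
}

test_that("reading parses well-formed rows and drops broken ones", {
  path <- tempfile(fileext = ".csv")
  write.csv(make_raw(2), path, row.names = FALSE)
  occ <- read_occurrences(path)
  expect_equal(nrow(occ), 2L)
  expect_equal(attr(occ, "report")$n_dropped, 0L)

  raw <- make_raw(3)
  raw$paleolat[2] <- NA
  occ <- read_occurrences(raw)
  expect_equal(nrow(occ), 2L)
  expect_equal(attr(occ, "report")$dropped_bad_coordinates, 1L)

  raw <- make_raw(3)
  raw$max_ma[3] <- 60 # younger than min_ma
  occ <- read_occurrences(raw)
  expect_equal(attr(occ, "report")$dropped_bad_ages, 1L)
})

test_that("reading enforces mandatory columns and non-empty input", {
  raw <- make_raw(2)
  raw$min_ma <- NULL
  expect_error(read_occurrences(raw), "min_ma")
  expect_error(read_occurrences(make_raw(2)[0, ]), "empty")
})

test_that("cleaning applies group, environment and rank exclusions", {
  raw <- make_raw(4)
  raw$group_tags[1] <- "Aves"
  raw$accepted_rank[2] <- "genus"
  raw$environment[3] <- "marine indet."
  occ <- read_occurrences(raw)
  out <- clean_occurrences(occ)
  expect_equal(nrow(out), 1L)
  rep <- attr(out, "report")
  expect_equal(rep$removed_excluded_group, 1L)
  expect_equal(rep$removed_rank, 1L)
  expect_equal(rep$removed_excluded_environment, 1L)

  # empty config is the identity
  empty <- exclusion_config(excluded_group_tags = character(0),
                            excluded_environments = character(0),
                            allowed_ranks = character(0))
  out2 <- clean_occurrences(occ, empty)
  expect_equal(out2$occurrence_id, occ$occurrence_id)

  # idempotence
  once <- clean_occurrences(occ)
  twice <- clean_occurrences(once)
  expect_equal(twice$occurrence_id, once$occurrence_id)
})

test_that("time binning follows the majority-overlap rule", {
  bins <- make_time_bins(80, 60, 10)
  raw <- make_raw(4)
  raw$max_ma <- c(72, 66, 75, 70) # ranges: 66-72, 64-66, 65-75, 70-70
  raw$min_ma <- c(66, 64, 65, 70)
  occ <- assign_time_bins(read_occurrences(raw), bins)
  # 66-72: 4/6 of the range in 60-70
  expect_equal(occ$bin_id[1], "bin_070_060")
  # full containment
  expect_equal(occ$bin_id[2], "bin_070_060")
  # exact 50/50 is dropped ("over 50%" is strict)
  expect_true(is.na(occ$bin_id[3]))
  # zero-length range on a boundary goes to the older bin
  expect_equal(occ$bin_id[4], "bin_080_070")
  expect_equal(attr(occ, "report")$n_dropped, 1L)
})

test_that("binning conserves records and ignores row order", {
  bins <- make_time_bins(100, 0, 10)
  set.seed(17)
  n <- 200
  raw <- make_raw(n)
  mid <- runif(n, 0, 100)
  h <- runif(n, 0, 12)
  raw$min_ma <- pmax(0, mid - h)
  raw$max_ma <- mid + h
  occ <- assign_time_bins(read_occurrences(raw), bins)
  rep <- attr(occ, "report")
  expect_equal(rep$n_binned + rep$n_dropped, n)
  expect_equal(sum(!is.na(occ$bin_id)), rep$n_binned)

  perm <- sample(n)
  occ2 <- assign_time_bins(read_occurrences(raw[perm, ]), bins)
  m1 <- setNames(occ$bin_id, occ$occurrence_id)
  m2 <- setNames(occ2$bin_id, occ2$occurrence_id)
  expect_identical(m1[names(m2)], m2)
})
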