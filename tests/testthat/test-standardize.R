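region_row <- function(mst = 2000, branch_frac = 0.3, refs = 20,
                       multiton = 0.25, members = "1 2 3",
                       bin_id = "b1", codes = "EU") {
  data.frame(bin_id = bin_id, members = members, mst_total_km = mst,
             mst_longest_km = mst * branch_frac, n_references = refs,
             multiton_ratio = multiton, region_codes = codes,
             dominant_region_code = strsplit(codes, " ")[[1]][1],
             stringsAsFactors = FALSE)
}

test_that("filtering keeps boundary passes and rejects out-of-window MSTs", {
  crit <- standardization_criteria(2000)
  pass <- region_row(mst = 2000, branch_frac = 0.39, refs = 20,
                     multiton = 0.25)
  expect_equal(nrow(filter_regions(pass, crit)), 1L)
  expect_equal(nrow(filter_regions(region_row(mst = 2250), crit)), 0L)
  expect_equal(nrow(filter_regions(region_row(branch_frac = 0.45), crit)), 0L)
  expect_equal(nrow(filter_regions(region_row(refs = 19), crit)), 0L)
  expect_equal(nrow(filter_regions(region_row(multiton = 0.2), crit)), 0L)
})

test_that("filtering is monotone under stricter criteria and idempotent", {
  set.seed(67)
  for (i in 1:20) {
    tab <- random_region_table(40)
    lax <- standardization_criteria(2000, mst_tolerance = 0.5,
                                    max_longest_branch_frac = 0.6,
                                    min_references = 10,
                                    min_multiton_ratio = 0.1)
    strict <- standardization_criteria(2000, mst_tolerance = 0.2,
                                       max_longest_branch_frac = 0.4,
                                       min_references = 20,
                                       min_multiton_ratio = 0.3)
    a <- filter_regions(tab, lax)
    b <- filter_regions(tab, strict)
    expect_true(all(b$members %in% a$members))
    expect_identical(filter_regions(a, lax), a)
  }
})

test_that("barrier rules remove regions spanning separated landmasses", {
  mids <- c(b1 = 100, b2 = 150)
  rules <- list(list(side_a = "SA", side_b = "AF", active_after_ma = 120))
  crossing_young <- region_row(bin_id = "b1", codes = "AF SA")
  crossing_old <- region_row(bin_id = "b2", codes = "AF SA")
  one_side <- region_row(bin_id = "b1", codes = "SA")
  tab <- rbind(crossing_young, crossing_old, one_side)
  out <- apply_barrier_rules(tab, rules, mids)
  expect_equal(nrow(out), 2L)
  expect_false(any(out$bin_id == "b1" & out$region_codes == "AF SA"))
})

test_that("clustering joins overlapping regions and separates disjoint ones", {
  a <- region_row(members = "1 2 3 4")
  b <- region_row(members = "3 4 5 6") # overlap 2/4 = 0.5
  two <- cluster_regions(rbind(a, b))
  expect_equal(length(unique(two$cluster_id)), 1L)

  c2 <- region_row(members = "10 11")
  out <- cluster_regions(rbind(a, c2))
  expect_equal(length(unique(out$cluster_id)), 2L)

  # chain transitivity: R1~R2, R2~R3, R1 and R3 disjoint
  r1 <- region_row(members = "1 2 3 4")
  r2 <- region_row(members = "3 4 5 6")
  r3 <- region_row(members = "5 6 7 8")
  chain <- cluster_regions(rbind(r1, r2, r3))
  expect_equal(length(unique(chain$cluster_id)), 1L)
})

test_that("clustering partitions regions and ignores input order", {
  set.seed(71)
  for (i in 1:20) {
    tab <- random_region_table(15)
    tab <- tab[!duplicated(tab$members), ]
    out <- cluster_regions(tab)
    expect_false(any(is.na(out$cluster_id)))
    perm <- sample(nrow(tab))
    out2 <- cluster_regions(tab[perm, ])
    key1 <- split(out$members, out$cluster_id)
    key2 <- split(out2$members, out2$cluster_id)
    norm <- function(x) sort(vapply(x, function(s)
      paste(sort(s), collapse = "|"), character(1)))
    expect_identical(norm(key1), norm(key2))
  }
})

test_that("cluster summaries report interpolated quartiles and NA handling", {
  tab <- rbind(region_row(members = "1 2"), region_row(members = "1 2 3"),
               region_row(members = "1 2 3 4"))
  tab$sqs_q0.6 <- c(1, 2, 3)
  tab$chao2 <- NA_real_
  cl <- cluster_regions(tab)
  sm <- summarize_clusters(cl, variables = c("sqs_q0.6", "chao2"))
  sq <- sm[sm$variable == "sqs_q0.6", ]
  expect_equal(sq$median, 2)
  expect_equal(sq$iqr, 1)
  expect_equal(sq$n_regions, 3L)
  ch <- sm[sm$variable == "chao2", ]
  expect_true(is.na(ch$median))
  expect_equal(ch$n_regions, 0L)

  single <- summarize_clusters(cluster_regions(region_row()),
                               variables = "mst_total_km")
  expect_equal(single$iqr, 0)
  expect_equal(single$median, 2000)
})
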