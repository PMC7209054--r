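test_that("coverage statistics match their closed forms", {
  cs <- coverage_stats(c(4, 3, 2, 1))
  expect_equal(cs$goods_u, 0.9, tolerance = 1e-9)
  expect_equal(cs$multiton_ratio, 0.75, tolerance = 1e-9)
  expect_equal(cs$coverage, 1 - (1 / 10) * (9 / (9 + 2)), tolerance = 1e-9)

  all_singl <- coverage_stats(c(1, 1, 1))
  expect_equal(all_singl$goods_u, 0)
  expect_equal(all_singl$multiton_ratio, 0)

  expect_equal(coverage_stats(c(5, 5))$coverage, 1)
  expect_error(coverage_stats(integer(0)), "empty")
})

test_that("SQS reproduces the observed point and respects bounds", {
  # single species: one species at any quorum
  expect_equal(sqs_richness(c(7), 0.6)$value, 1)
  expect_no_error(sqs_richness(c(1), 0.4)) # lone singleton must not error

  counts <- c(4, 3, 2, 1)
  ref_cov <- coverage_stats(counts)$coverage
  at_ref <- sqs_richness(counts, ref_cov)
  expect_equal(at_ref$value, 4)

  below <- sqs_richness(counts, 0.5)
  expect_lte(below$value, 4)
  expect_gt(below$value, 0)
})

test_that("SQS interpolation matches the resampling oracle on a fixture", {
  counts <- c(9, 5, 3, 2, 1, 1, 1)
  set.seed(31)
  or <- mc_rarefaction_oracle(counts, m = 10, reps = 5000)
  expect_lt(abs(palaeoreg:::rarefied_richness(counts, 10) - or$richness),
            3 * or$richness_se + 1e-9)
  expect_lt(abs(palaeoreg:::rarefied_coverage(counts, 10) - or$coverage),
            3 * or$coverage_se + 1e-9)
})

test_that("SQS is non-decreasing in the quorum", {
  set.seed(37)
  for (i in 1:10) {
    counts <- sample(1:12, sample(3:15, 1), replace = TRUE)
    qs <- c(0.3, 0.5, 0.7, 0.9)
    vals <- vapply(qs, function(q) sqs_richness(counts, q)$value, numeric(1))
    ok <- !is.na(vals)
    expect_true(all(diff(vals[ok]) >= -1e-9))
  }
})

test_that("SQS flags degenerate and deep-extrapolation cases", {
  all_singl <- sqs_richness(c(1, 1, 1), 0.9)
  expect_true(is.na(all_singl$value))
  expect_true("undefined_fallback" %in% all_singl$flags)
  expect_error(sqs_richness(c(2, 1), 1.2), "quorum")
  expect_error(sqs_richness(c(2, 1), 0), "quorum")
  # a high quorum on a poorly covered sample forces deep extrapolation
  deep <- sqs_richness(c(2, 2, 1, 1, 1, 1, 1, 1), 0.99)
  expect_true(is.na(deep$value) ||
                "extrapolated_beyond_2n" %in% deep$flags ||
                deep$params$m_target <= 2 * 10)
})

test_that("Chao 2 follows the classical and bias-corrected forms", {
  est <- chao2(c(1, 1, 2, 3, 4), m = 4)
  expect_equal(est$value, 6.5, tolerance = 1e-9)

  no_singl <- chao2(c(2, 3, 2), m = 5)
  expect_equal(no_singl$value, 3)

  one_unit <- chao2(c(1, 1, 1), m = 1)
  expect_equal(one_unit$value, 3) # (m-1)/m multiplier is zero

  q2_zero <- chao2(c(1, 1, 3), m = 4)
  expect_equal(q2_zero$value, 3 + (3 / 4) * 2 * 1 / 2, tolerance = 1e-9)
  expect_true("bias_corrected_q2_zero" %in% q2_zero$flags)
})

test_that("squares estimator matches its formula and degenerates safely", {
  est <- squares_richness(c(3, 2, 1))
  expect_equal(est$value, 3 + 1 * 14 / (36 - 3), tolerance = 1e-9)

  expect_equal(squares_richness(c(4, 2, 3))$value, 3) # f1 = 0

  degen <- squares_richness(c(1, 1, 1))
  expect_true(is.na(degen$value))
  expect_true("undefined_fallback" %in% degen$flags)
})

test_that("extrapolators never fall below observed richness", {
  set.seed(41)
  for (i in 1:25) {
    counts <- sample(1:9, sample(3:20, 1), replace = TRUE)
    s_obs <- length(counts)
    sq <- squares_richness(counts)$value
    if (!is.na(sq)) expect_gte(sq, s_obs - 1e-9)
    units <- pmin(counts, sample(3:6, 1))
    ch <- chao2(units, m = max(units) + 2L)$value
    expect_gte(ch, s_obs - 1e-9)
  }
})

test_that("grid-cell rarefaction applies the MST-proportional quota", {
  # quota arithmetic: 3 cells per 1000 km on a 2000 km MST -> 6 cells
  set.seed(43)
  occ <- data.frame(
    paleo_lon = rep(seq(0, 14, by = 2), each = 8),
    paleo_lat = 0,
    taxon_name = sample(paste("sp", 1:30), 64, replace = TRUE))
  est <- gcr_sqs(occ, mst_total_km = 2000, q = 0.6, quota_per_1000km = 3,
                 trials = 5, seed = 1)
  expect_equal(est$params$quota, 6)
  expect_false(is.na(est$value))

  # fewer occupied cells than the quota -> missing
  small <- occ[occ$paleo_lon < 6, ]
  est2 <- gcr_sqs(small, mst_total_km = 2000, q = 0.6, quota_per_1000km = 3,
                  trials = 5, seed = 1)
  expect_true(is.na(est2$value))
  expect_true("below_quota" %in% est2$flags)

  # identical cell contents: one trial equals fifty
  same <- do.call(rbind, lapply(seq(0, 40, by = 10), function(shift)
    data.frame(paleo_lon = shift, paleo_lat = 0,
               taxon_name = paste("sp", c(1, 1, 2, 2, 3, 4, 5)))))
  e1 <- gcr_sqs(same, 2000, 0.6, 1, trials = 1, seed = 2)
  e50 <- gcr_sqs(same, 2000, 0.6, 1, trials = 50, seed = 2)
  expect_equal(e1$value, e50$value, tolerance = 1e-12)
})

test_that("the GCR trial mean is stable under doubling the trial count", {
  set.seed(47)
  occ <- do.call(rbind, lapply(seq(0, 27, by = 3), function(shift)
    data.frame(paleo_lon = shift, paleo_lat = 0,
               taxon_name = sample(paste("sp", 1:40), 25, replace = TRUE))))
  e25 <- gcr_sqs(occ, mst_total_km = 2500, q = 0.6, quota_per_1000km = 2,
                 trials = 25, seed = 3)
  e50 <- gcr_sqs(occ, mst_total_km = 2500, q = 0.6, quota_per_1000km = 2,
                 trials = 50, seed = 3)
  expect_lt(abs(e50$value - e25$value) / e25$value, 0.02)
})
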