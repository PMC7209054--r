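test_that("world scenarios produce their configured trajectories", {
  flat <- simulate_world(world_config(n_bins = 10, scenario = "flat",
                                      regional_pool_size = 100,
                                      n_latent_regions = 2, rng_seed = 1))
  expect_true(all(flat$true_richness$pool_size == 100))

  exp_cfg <- world_config(n_bins = 8, scenario = "expansionist",
                          regional_pool_size = 50, growth_rate = 0.02,
                          n_latent_regions = 1, rng_seed = 2)
  ew <- simulate_world(exp_cfg)
  sizes <- ew$true_richness$pool_size
  expected <- round(50 * exp(0.02 * 10 * (seq_len(8) - 1)))
  expect_equal(sizes, expected)

  shift <- simulate_world(world_config(n_bins = 16,
                                       scenario = "constrained_with_shift",
                                       regional_pool_size = 100,
                                       shift_factor = 2.5, boundary_ma = 66,
                                       n_latent_regions = 1, rng_seed = 3))
  agg <- tapply(shift$true_richness$pool_size,
                shift$true_richness$bin_id, unique)
  mids <- setNames(shift$bins$midpoint_ma, shift$bins$bin_id)
  pre <- unlist(agg[names(agg)[mids[names(agg)] > 66]])
  post <- unlist(agg[names(agg)[mids[names(agg)] < 66]])
  expect_equal(as.numeric(unique(post)) / as.numeric(unique(pre)), 2.5)
})

test_that("sampling is deterministic and round-trips losslessly", {
  sc <- make_scenario("flat", seed = 5)
  w <- simulate_world(sc$world)
  r1 <- sample_fossil_record(w, sc$sampling)
  r2 <- sample_fossil_record(w, sc$sampling)
  expect_identical(r1$occurrences, r2$occurrences)

  occ <- read_occurrences(r1$occurrences)
  expect_equal(nrow(occ), nrow(r1$occurrences))
  expect_equal(attr(occ, "report")$n_dropped, 0L)
})

test_that("generated records satisfy the occurrence invariants", {
  sc <- make_scenario("constrained_shift", seed = 8)
  rec <- sample_fossil_record(simulate_world(sc$world), sc$sampling)
  occ <- rec$occurrences
  expect_true(all(occ$max_ma >= occ$min_ma))
  expect_true(all(abs(occ$paleolng) <= 180))
  expect_true(all(abs(occ$paleolat) <= 90))
  expect_true(all(nzchar(occ$accepted_name)))
  expect_true(all(occ$min_ma >= 0))
  # references partition collections: each collection has one reference
  per_coll <- tapply(occ$reference_no, occ$collection_no,
                     function(x) length(unique(x)))
  expect_true(all(per_coll == 1L))
})

test_that("a stable window leaves spatial extent trendless", {
  sc <- make_scenario("flat", seed = 11)
  w <- simulate_world(sc$world)
  rec <- sample_fossil_record(w, sc$sampling)
  occ <- assign_time_bins(read_occurrences(rec$occurrences), w$bins)
  occ <- occ[!is.na(occ$bin_id), ]
  g <- build_grid(100)
  msts <- vapply(w$bins$bin_id[1:10], function(b) {
    pts <- spatial_points(occ[occ$bin_id == b, ], g)
    minimum_spanning_tree(pts$lon, pts$lat)$total_km
  }, numeric(1))
  rho <- suppressWarnings(cor(seq_along(msts), msts, method = "spearman"))
  expect_lt(abs(rho), 0.5)
})

test_that("a growing window expands occupied-cell counts bin over bin", {
  # a dense field of latent regions, so window growth adds sampled area
  # every bin instead of in rare jumps
  w <- simulate_world(world_config(
    n_bins = 10, scenario = "flat", regional_pool_size = 80,
    n_latent_regions = 80, region_extent_km = 6000,
    min_separation_km = 400, rng_seed = 31))
  rec <- sample_fossil_record(w, sampling_config(
    collections_per_region = 25, spatial_window_km = 2400,
    window_growth = 0.017, cluster_sd_km = 350,
    occurrences_per_collection = 3, rng_seed = 32))
  occ <- assign_time_bins(read_occurrences(rec$occurrences), w$bins)
  occ <- occ[!is.na(occ$bin_id), ]
  cells <- vapply(w$bins$bin_id, function(b)
    count_occupied_cells(occ[occ$bin_id == b, ], 500), integer(1))
  expect_gte(sum(diff(cells) > 0), 8)
})

test_that("zero occurrences per collection yields an empty table", {
  w <- simulate_world(world_config(n_bins = 3, n_latent_regions = 1,
                                   rng_seed = 1))
  rec <- sample_fossil_record(w, sampling_config(
    collections_per_region = 5, occurrences_per_collection = 0,
    rng_seed = 2))
  expect_equal(nrow(rec$occurrences), 0L)
})

test_that("scenario factory validates names and wires the bias demo", {
  expect_error(make_scenario("nope"), "flat")
  fl <- make_scenario("flat", seed = 1)
  expect_equal(fl$world$scenario, "flat")
  bd <- make_scenario("bias_demo", seed = 1)
  expect_equal(bd$world$scenario, "flat")
  expect_gt(bd$sampling$window_growth, 0)
  expect_true(is.finite(bd$sampling$spatial_window_km))
  ex <- make_scenario("expansionist", seed = 1)
  expect_gt(ex$world$growth_rate, 0)
})
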