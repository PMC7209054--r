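test_that("three collinear points yield exactly the hand-enumerated regions", {
  # A-B closer than B-C: growth gives {A,B}, {B,C}, {A,B,C}
  pts <- data.frame(cell_id = c(101L, 102L, 103L),
                    lon = c(0, 1, 3), lat = c(0, 0, 0))
  rs <- enumerate_regions(pts, seed = 1)
  keys <- sort(vapply(rs$regions, function(r)
    paste(sort(r$members), collapse = " "), character(1)))
  expect_identical(keys, c("101 102", "101 102 103", "102 103"))
})

test_that("the full point set is always saved and duplicates are discarded", {
  set.seed(53)
  for (i in 1:5) {
    pts <- random_point_set(sample(4:8, 1))
    rs <- enumerate_regions(pts, seed = i)
    keys <- vapply(rs$regions, function(r)
      paste(sort(r$members), collapse = " "), character(1))
    expect_identical(anyDuplicated(keys), 0L)
    expect_true(paste(sort(pts$cell_id), collapse = " ") %in% keys)
    # union of the size-2 regions covers every point
    two <- rs$regions[vapply(rs$regions, function(r)
      length(r$members) == 2L, logical(1))]
    expect_setequal(unique(unlist(lapply(two, `[[`, "members"))), pts$cell_id)
  }
})

test_that("enumeration is deterministic given a seed and warns below 2 points", {
  pts <- random_point_set(6)
  a <- enumerate_regions(pts, seed = 7)
  b <- enumerate_regions(pts, seed = 7)
  expect_identical(a, b)
  expect_warning(out <- enumerate_regions(pts[1, ], seed = 1), "fewer than 2")
  expect_length(out$regions, 0L)
})

test_that("enumeration equals the exhaustive oracle on small point sets", {
  set.seed(59)
  for (i in 1:20) {
    pts <- random_point_set(sample(3:7, 1))
    D <- great_circle_matrix(pts$lon, pts$lat)
    oracle <- region_enumeration_oracle(D)
    rs <- enumerate_regions(pts, seed = i)
    keys <- sort(vapply(rs$regions, function(r)
      paste(sort(match(r$members, pts$cell_id)), collapse = " "),
      character(1)))
    expect_identical(keys, oracle)
  }
})

test_that("tied distances keep output inside the exhaustive oracle set", {
  # equilateral-ish: B and C equidistant from A
  pts <- data.frame(cell_id = 1:3, lon = c(0, 2, 2), lat = c(0, 1, -1))
  D <- great_circle_matrix(pts$lon, pts$lat)
  oracle <- region_enumeration_oracle(D)
  for (seed in 1:5) {
    rs <- enumerate_regions(pts, seed = seed)
    keys <- vapply(rs$regions, function(r)
      paste(sort(match(r$members, pts$cell_id)), collapse = " "), character(1))
    expect_true(all(keys %in% oracle))
  }
})

test_that("accretion totals equal the true MST of each saved region", {
  set.seed(61)
  for (i in 1:5) {
    pts <- random_point_set(sample(5:9, 1))
    D <- great_circle_matrix(pts$lon, pts$lat)
    rs <- enumerate_regions(pts, seed = i)
    for (r in rs$regions) {
      idx <- match(r$members, pts$cell_id)
      mst <- minimum_spanning_tree(D[idx, idx, drop = FALSE])
      expect_equal(r$mst_total_km, mst$total_km, tolerance = 1e-9)
      expect_equal(r$mst_longest_km, mst$longest_km, tolerance = 1e-9)
    }
  }
})

test_that("characterization fills tallies, occupancy and estimates", {
  pts <- data.frame(cell_id = NA, lon = c(0, 1.2), lat = c(0, 0))
  g100 <- build_grid(100)
  pts$cell_id <- assign_cell(g100, pts$lon, pts$lat)
  occ <- data.frame(
    occurrence_id = 1:6,
    collection_id = c(1, 1, 2, 2, 3, 3),
    taxon_name = c("a", "b", "a", "c", "c", "d"),
    paleo_lon = c(0, 0, 0, 0, 1.2, 1.2), paleo_lat = 0,
    reference_id = c("r1", "r1", "r2", "r2", "r2", "r2"),
    region_code = "EU")
  skel <- list(list(members = pts$cell_id))
  tab <- characterize_regions(skel, pts, occ, bin_id = "b1",
                              spacings = c(100, 5000))
  expect_equal(tab$n_references, 2L)
  expect_equal(tab$cells_100km, 2L)
  expect_equal(tab$cells_5000km, 1L)
  expect_equal(tab$n_collections, 3L)
  expect_equal(tab$face_value, 4)
  expect_equal(tab$dominant_region_code, "EU")
  # deterministic: same call twice gives the same row
  tab2 <- characterize_regions(skel, pts, occ, bin_id = "b1",
                               spacings = c(100, 5000))
  expect_identical(tab, tab2)
})
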