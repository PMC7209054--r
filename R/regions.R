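#' Enumerate nested palaeogeographical regions
#'
#' Implements the spatial subsampling algorithm: from every occupied-cell
#' starting point, repeatedly add the unsampled point with minimum
#' great-circle distance to the current member set (single linkage; ties
#' broken uniformly at random with the supplied seed), saving every
#' intermediate set of two or more points as a candidate region. Exact
#' duplicate member sets arising from different starts are discarded.
#'
#' The accretion rule is Prim's algorithm, so the running sum of accretion
#' distances is the minimum-spanning-tree length of each saved prefix;
#' these totals are attached to the skeletons and let downstream code
#' pre-filter regions by spatial extent before full characterization.
#'
#' @param points data.frame from [spatial_points()] (`cell_id`, `lon`,
#'   `lat`).
#' @param seed Integer seed for tie-breaking; recorded in the output.
#' @return List of class `region_set`: `regions` (list; each has
#'   `members` — cell ids in accretion order —, `mst_total_km`,
#'   `mst_longest_km`), `seed`, `n_points`.
#' @export
enumerate_regions <- function(points, seed = 1L) {
  p <- nrow(points)
  if (p < 2L) {
    warning("fewer than 2 spatial points; no regions enumerated")
    return(structure(list(regions = list(), seed = seed, n_points = p),
                     class = "region_set"))
  }
  D <- great_circle_matrix(points$lon, points$lat)
  tol <- 1e-9
  seen <- new.env(hash = TRUE, parent = emptyenv())
  regions <- list()
  nreg <- 0L
  with_seed(seed, {
    for (s in seq_len(p)) {
      order_idx <- integer(p)
      order_idx[1L] <- s
      dmin <- D[s, ]
      dmin[s] <- Inf
      acc_total <- 0
      acc_longest <- 0
      in_set <- rep(FALSE, p)
      in_set[s] <- TRUE
      for (k in 2:p) {
        m <- min(dmin)
        cand <- which(dmin <= m + tol)
        j <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
        order_idx[k] <- j
        acc_total <- acc_total + dmin[j]
        acc_longest <- max(acc_longest, dmin[j])
        in_set[j] <- TRUE
        dmin <- pmin(dmin, D[j, ])
        dmin[in_set] <- Inf
        key <- paste(sort.int(order_idx[1:k]), collapse = " ")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          nreg <- nreg + 1L
          regions[[nreg]] <- list(
            members = points$cell_id[order_idx[1:k]],
            idx = order_idx[1:k],
            mst_total_km = acc_total,
            mst_longest_km = acc_longest)
        }
      }
    }
  })
  structure(list(regions = regions, seed = seed, n_points = p),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region set: %d regions from %d spatial points (seed %s)\n",
              length(x$regions), x$n_points, format(x$seed)))
  invisible(x)
}

#' Characterize palaeogeographical regions
#'
#' Fills the full metadata for region skeletons: the recomputed MST,
#' occupied-cell counts across grid spacings, occurrence/collection/
#' reference tallies, frequency-based coverage statistics, and the four
#' richness estimates (face value, SQS at each quorum, Chao 2 over
#' collections, squares). Estimator failures are recorded as NA, never
#' raised.
#'
#' @param regions A `region_set` (or plain list of skeletons with
#'   `members`).
#' @param points The `spatial_points()` table used for enumeration.
#' @param occurrences The bin's occurrence data.frame.
#' @param bin_id Bin label stamped on each output row.
#' @param spacings Grid spacings (km) for occupied-cell counts.
#' @param quorums SQS quorum levels.
#' @param gcr Optional list of GCR settings:
#'   `quota_per_1000km` (vector), `q`, `cell_spacing_km`, `trials`.
#' @param seed Seed for GCR subsampling draws.
#' @param base_grid Grid that defined the spatial points (default 100 km).
#' @return data.frame, one row per region; `members` is a space-separated
#'   cell-id list.
#' @export
characterize_regions <- function(regions, points, occurrences, bin_id = NA,
                                 spacings = c(100, 200, 500, 1000, 5000),
                                 quorums = c(0.4, 0.6, 0.8),
                                 gcr = NULL, seed = NULL,
                                 base_grid = build_grid(100)) {
  skel <- if (inherits(regions, "region_set")) regions$regions else regions
  if (length(skel) == 0L)
    return(data.frame())
  occ_cell <- assign_cell(base_grid, occurrences$paleo_lon, occurrences$paleo_lat)
  cell_grids <- lapply(spacings, build_grid)
  names(cell_grids) <- paste0("cells_", spacings, "km")
  # per-occurrence cell id at every spacing, computed once
  occ_cells_by_spacing <- lapply(cell_grids, function(g)
    assign_cell(g, occurrences$paleo_lon, occurrences$paleo_lat))
  D <- great_circle_matrix(points$lon, points$lat)
  point_row <- stats::setNames(seq_len(nrow(points)), points$cell_id)
  gcr_seeds <- if (!is.null(gcr))
    spawn_seeds(seed %||% 1L, length(skel)) else NULL

  rows <- vector("list", length(skel))
  for (i in seq_along(skel)) {
    members <- skel[[i]]$members
    ridx <- point_row[as.character(members)]
    mst <- minimum_spanning_tree(D[ridx, ridx, drop = FALSE])
    in_region <- occ_cell %in% members
    occ <- occurrences[in_region, , drop = FALSE]
    row <- data.frame(
      bin_id = bin_id,
      members = paste(sort.int(members), collapse = " "),
      n_points = length(members),
      mst_total_km = mst$total_km,
      mst_longest_km = mst$longest_km,
      n_occurrences = nrow(occ))
    for (nm in names(occ_cells_by_spacing))
      row[[nm]] <- length(unique(occ_cells_by_spacing[[nm]][in_region]))
    row$n_collections <- length(unique(occ$collection_id))
    row$n_references <- if ("reference_id" %in% names(occ))
      length(unique(occ$reference_id[!is.na(occ$reference_id)])) else NA_integer_
    row$dominant_region_code <- if ("region_code" %in% names(occ))
      modal_value(occ$region_code) else NA_character_
    row$region_codes <- if ("region_code" %in% names(occ))
      paste(sort(unique(occ$region_code[!is.na(occ$region_code)])),
            collapse = " ") else NA_character_
    if (nrow(occ) > 0L) {
      freq <- frequency_vector(occ$taxon_name)
      cs <- coverage_stats(freq)
      row$goods_u <- cs$goods_u
      row$multiton_ratio <- cs$multiton_ratio
      row$coverage <- cs$coverage
      row$face_value <- cs$s_obs
      for (q in quorums)
        row[[sprintf("sqs_q%g", q)]] <-
          tryCatch(sqs_richness(freq, q)$value, error = function(e) NA_real_)
      units <- tapply(occ$collection_id, occ$taxon_name,
                      function(x) length(unique(x)))
      row$chao2 <- tryCatch(
        chao2(as.integer(units), length(unique(occ$collection_id)))$value,
        error = function(e) NA_real_)
      row$squares <- tryCatch(squares_richness(freq)$value,
                              error = function(e) NA_real_)
      if (!is.null(gcr)) {
        for (quota in gcr$quota_per_1000km) {
          key <- sprintf("sqs_gcr%g_q%g", quota, gcr$q %||% 0.6)
          row[[key]] <- tryCatch(
            gcr_sqs(occ, mst$total_km, gcr$q %||% 0.6, quota,
                    cell_spacing_km = gcr$cell_spacing_km %||% 200,
                    trials = gcr$trials %||% 50,
                    seed = gcr_seeds[i])$value,
            error = function(e) NA_real_)
        }
      }
    } else {
      row$goods_u <- row$multiton_ratio <- row$coverage <- NA_real_
      row$face_value <- 0L
      for (q in quorums) row[[sprintf("sqs_q%g", q)]] <- NA_real_
      row$chao2 <- row$squares <- NA_real_
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
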