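#' World configuration for the synthetic fossil record
#'
#' Defines the true biology: per-bin species pools held in a set of latent
#' geographic regions (disc-shaped neighbourhoods on the sphere), a
#' species-abundance distribution, and a diversity trajectory scenario —
#' `"flat"` (constant pools), `"expansionist"` (pools grow exponentially
#' toward the present) or `"constrained_with_shift"` (constant pools with
#' one multiplicative jump at `boundary_ma`).
#'
#' @param n_bins Number of equal-length time bins.
#' @param bin_length_myr Bin length (Myr).
#' @param scenario One of "flat", "expansionist", "constrained_with_shift".
#' @param regional_pool_size True species per latent region per bin (oldest
#'   bin, before any growth/shift).
#' @param growth_rate Per-Myr exponential pool growth (expansionist).
#' @param shift_factor Multiplicative pool jump at the boundary
#'   (constrained_with_shift).
#' @param boundary_ma Age of the phase shift (default 66).
#' @param n_latent_regions Number of latent regions.
#' @param region_extent_km Maximum distance of latent-region centres from
#'   the anchor point.
#' @param min_separation_km Minimum separation between centres.
#' @param region_overlap Probability that a newly added species is
#'   recruited from another region's pool instead of being new to the
#'   world (shared-species fraction controlling beta diversity).
#' @param turnover Fraction of each region's pool replaced per bin.
#' @param sad Species-abundance distribution: `list(type = "log_series",
#'   x = ...)` or `list(type = "lognormal", meanlog = , sdlog = )`.
#' @param anchor_lon,anchor_lat Anchor of the sampled domain.
#' @param rng_seed Seed.
#' @return List of class `world_config`.
#' @export
world_config <- function(n_bins = 16, bin_length_myr = 10,
                         scenario = c("flat", "expansionist",
                                      "constrained_with_shift"),
                         regional_pool_size = 120,
                         growth_rate = 0, shift_factor = 2.5,
                         boundary_ma = 66,
                         n_latent_regions = 3,
                         region_extent_km = 8000,
                         min_separation_km = 2500,
                         region_overlap = 0.10,
                         turnover = 0.25,
                         sad = list(type = "log_series", x = 0.99),
                         anchor_lon = 0, anchor_lat = 0,
                         rng_seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(regional_pool_size >= 1, growth_rate >= 0, shift_factor > 0,
            n_latent_regions >= 1)
  structure(as.list(environment()), class = "world_config")
}

#' Sampling configuration for the synthetic fossil record
#'
#' Defines the observation process: how many fossil collections each
#' sampled latent region yields per bin, the spatial window (a spherical
#' cap around the anchor) that decides which latent regions are sampled
#' at all — its radius may grow exponentially toward the present, which
#' is the spatial bias under study —, the scatter of collections around region
#' centres, occurrences per collection, the partition of collections into
#' literature references, and age-range slop across bin boundaries.
#'
#' Collections are budgeted per sampled region (not globally): real
#' fossil collections are clustered, and a growing window adds clusters
#' rather than diluting a fixed worldwide budget.
#'
#' @param collections_per_region Collections per sampled region per bin.
#' @param collections_growth Per-Myr exponential growth of that number.
#' @param spatial_window_km Initial window diameter (km); `Inf` samples
#'   every region in every bin.
#' @param window_growth Per-Myr exponential growth rate of the window
#'   radius toward the present.
#' @param cluster_sd_km Gaussian scatter (km) of collections around their
#'   region centre.
#' @param occurrences_per_collection Mean occurrences per collection
#'   (1 + Poisson(mean - 1)).
#' @param collections_per_reference Mean collections per literature
#'   reference (1 + Poisson(mean - 1) sized publication groups).
#' @param age_slop_frac Half-width of occurrence age ranges, as a
#'   fraction of bin length (uniform on [0, frac * bin]).
#' @param frac_genus_rank Fraction of occurrences downgraded to genus
#'   rank (exercises the rank filter).
#' @param frac_excluded_group Fraction tagged with an excluded higher
#'   taxon (exercises the group filter).
#' @param rng_seed Seed.
#' @return List of class `sampling_config`.
#' @export
sampling_config <- function(collections_per_region = 40,
                            collections_growth = 0,
                            spatial_window_km = Inf,
                            window_growth = 0,
                            cluster_sd_km = 200,
                            occurrences_per_collection = 3,
                            collections_per_reference = 1.3,
                            age_slop_frac = 0.2,
                            frac_genus_rank = 0.03,
                            frac_excluded_group = 0.02,
                            rng_seed = 2L) {
  stopifnot(collections_per_region > 0, occurrences_per_collection >= 0,
            collections_per_reference >= 1, cluster_sd_km > 0)
  structure(as.list(environment()), class = "sampling_config")
}

# draw per-species abundance weights from the configured SAD
.draw_sad_weights <- function(n, sad) {
  if (sad$type == "log_series") {
    x <- sad$x %||% 0.99
    k <- 1:5000
    p <- x^k / k
    sample(k, n, replace = TRUE, prob = p)
  } else if (sad$type == "lognormal") {
    stats::rlnorm(n, sad$meanlog %||% 0, sad$sdlog %||% 1)
  } else stop("unknown SAD type: ", sad$type)
}

# scatter latent region centres in a disc around the anchor, keeping a
# minimum separation where geometrically possible
.place_regions <- function(cfg) {
  r_earth <- 6371.0088
  centres <- matrix(NA_real_, cfg$n_latent_regions, 2)
  codes <- rep(c("NAm", "EU", "AS", "SA", "AF", "AUS", "NZ"),
               length.out = cfg$n_latent_regions)
  for (i in seq_len(cfg$n_latent_regions)) {
    for (try in 1:500) {
      d <- sqrt(stats::runif(1)) * cfg$region_extent_km
      theta <- stats::runif(1, 0, 2 * pi)
      # move distance d from the anchor along bearing theta (spherical)
      delta <- d / r_earth
      lat1 <- cfg$anchor_lat * pi / 180
      lon1 <- cfg$anchor_lon * pi / 180
      lat2 <- asin(sin(lat1) * cos(delta) + cos(lat1) * sin(delta) * cos(theta))
      lon2 <- lon1 + atan2(sin(theta) * sin(delta) * cos(lat1),
                           cos(delta) - sin(lat1) * sin(lat2))
      lon2 <- ((lon2 * 180 / pi + 180) %% 360) - 180
      lat2 <- lat2 * 180 / pi
      if (i == 1L) { centres[i, ] <- c(lon2, lat2); break }
      sep <- great_circle_km(lon2, lat2, centres[1:(i - 1), 1],
                             centres[1:(i - 1), 2])
      if (all(sep >= cfg$min_separation_km) || try == 500L) {
        centres[i, ] <- c(lon2, lat2); break
      }
    }
  }
  data.frame(region_id = seq_len(cfg$n_latent_regions),
             lon = centres[, 1], lat = centres[, 2], code = codes,
             dist_from_anchor_km = great_circle_km(
               cfg$anchor_lon, cfg$anchor_lat, centres[, 1], centres[, 2]))
}

#' Simulate the true world
#'
#' Builds per-bin, per-latent-region species pools with the configured
#' diversity trajectory. Species identities persist across bins subject
#' to turnover, and a configurable fraction of new recruits is shared
#' with other regions (beta-diversity control).
#'
#' @param cfg A [world_config()].
#' @return List of class `true_world`: `config`, `bins`, `regions`
#'   (centre coordinates and codes), `pools` (pools[[bin]][[region]] =
#'   data.frame `species`, `weight`), `true_richness` (data.frame
#'   bin_id, region_id, pool_size).
#' @export
simulate_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  bins <- make_time_bins(cfg$n_bins * cfg$bin_length_myr, 0,
                         cfg$bin_length_myr)
  with_seed(cfg$rng_seed, {
    regions <- .place_regions(cfg)
    elapsed <- bins$midpoint_ma[1L] - bins$midpoint_ma # Myr since oldest bin
    target <- switch(cfg$scenario,
      flat = rep(cfg$regional_pool_size, cfg$n_bins),
      expansionist = round(cfg$regional_pool_size *
                             exp(cfg$growth_rate * elapsed)),
      constrained_with_shift = round(cfg$regional_pool_size *
        ifelse(bins$midpoint_ma < cfg$boundary_ma, cfg$shift_factor, 1)))
    target <- pmax(1L, as.integer(target))
    species_counter <- 0L
    pools <- vector("list", cfg$n_bins)
    truth <- list()
    prev <- vector("list", cfg$n_latent_regions)
    for (b in seq_len(cfg$n_bins)) {
      pools[[b]] <- vector("list", cfg$n_latent_regions)
      for (r in seq_len(cfg$n_latent_regions)) {
        keep <- if (is.null(prev[[r]])) {
          data.frame(species = character(0), weight = numeric(0))
        } else {
          n_keep <- min(nrow(prev[[r]]),
                        round((1 - cfg$turnover) * target[b]))
          if (n_keep > 0L) prev[[r]][sample.int(nrow(prev[[r]]), n_keep), ]
          else prev[[r]][0L, ]
        }
        n_new <- target[b] - nrow(keep)
        new_names <- character(0)
        if (n_new > 0L) {
          shared <- stats::runif(n_new) < cfg$region_overlap
          donor_pool <- unlist(lapply(seq_len(cfg$n_latent_regions)[-r],
                                      function(rr) {
            p <- if (b > 1L) pools[[b]][[rr]] %||% prev[[rr]] else prev[[rr]]
            if (is.null(p)) character(0) else p$species
          }))
          donor_pool <- setdiff(donor_pool, keep$species)
          for (j in seq_len(n_new)) {
            if (shared[j] && length(donor_pool) > 0L) {
              pick <- donor_pool[sample.int(length(donor_pool), 1L)]
              donor_pool <- setdiff(donor_pool, pick)
              new_names <- c(new_names, pick)
            } else {
              species_counter <- species_counter + 1L
              new_names <- c(new_names, sprintf("Taxon sp%05d", species_counter))
            }
          }
        }
        pool <- rbind(keep, data.frame(
          species = new_names,
          weight = if (n_new > 0L) .draw_sad_weights(n_new, cfg$sad)
                   else numeric(0)))
        rownames(pool) <- NULL
        pools[[b]][[r]] <- pool
        truth[[length(truth) + 1L]] <- data.frame(
          bin_id = bins$bin_id[b], region_id = r, pool_size = nrow(pool))
      }
      prev <- pools[[b]]
    }
    structure(list(config = cfg, bins = bins, regions = regions,
                   pools = pools,
                   true_richness = do.call(rbind, truth)),
              class = "true_world")
  })
}

#' Sample a fossil occurrence record from a simulated world
#'
#' The observation process: per bin, latent regions whose centres fall
#' inside the (possibly growing) spatial window are sampled; each yields
#' a budget of collections scattered around its centre; occurrences are
#' drawn per collection from the region's SAD-weighted pool; collections
#' are partitioned into literature references; age ranges get uniform
#' slop across bin boundaries. The output is a PBDB-dialect occurrence
#' table that round-trips through [read_occurrences()].
#'
#' @param world A `true_world` from [simulate_world()].
#' @param cfg A [sampling_config()].
#' @return List of class `synthetic_record`: `occurrences` (data.frame in
#'   PBDB columns), `truth` (per-bin window radius, sampled regions, true
#'   pool sizes, seeds).
#' @export
sample_fossil_record <- function(world, cfg) {
  stopifnot(inherits(world, "true_world"), inherits(cfg, "sampling_config"))
  wc <- world$config
  bins <- world$bins
  km_per_deg <- 111.19493
  with_seed(cfg$rng_seed, {
    chunks <- list()
    truth_rows <- list()
    coll_no <- 0L; ref_no <- 0L
    elapsed <- bins$midpoint_ma[1L] - bins$midpoint_ma
    for (b in seq_len(nrow(bins))) {
      window_r <- if (is.infinite(cfg$spatial_window_km)) Inf else
        (cfg$spatial_window_km / 2) * exp(cfg$window_growth * elapsed[b])
      sampled <- which(world$regions$dist_from_anchor_km <= window_r)
      if (length(sampled) == 0L)
        sampled <- which.min(world$regions$dist_from_anchor_km)
      n_coll_region <- max(1L, round(cfg$collections_per_region *
                                       exp(cfg$collections_growth * elapsed[b])))
      coll_id <- sp_name <- coll_lon <- coll_lat <- coll_age <- coll_h <-
        coll_code <- coll_region <- list()
      bin_coll_ids <- integer(0)
      for (r in sampled) {
        pool <- world$pools[[b]][[r]]
        centre <- world$regions[r, ]
        for (ci in seq_len(n_coll_region)) {
          n_occ <- if (cfg$occurrences_per_collection <= 0) 0L else
            1L + stats::rpois(1, max(0, cfg$occurrences_per_collection - 1))
          if (n_occ == 0L) next
          coll_no <- coll_no + 1L
          bin_coll_ids <- c(bin_coll_ids, coll_no)
          lat <- centre$lat + stats::rnorm(1, 0, cfg$cluster_sd_km) / km_per_deg
          lat <- max(-90, min(90, lat))
          lon <- centre$lon + stats::rnorm(1, 0, cfg$cluster_sd_km) /
            (km_per_deg * max(0.05, cos(lat * pi / 180)))
          lon <- ((lon + 180) %% 360) - 180
          sp_idx <- unique(sample.int(nrow(pool), min(n_occ, nrow(pool)),
                                      prob = pool$weight, replace = TRUE))
          k <- length(sp_idx)
          t_true <- stats::runif(1, bins$late_ma[b], bins$early_ma[b])
          j <- length(coll_id) + 1L
          coll_id[[j]] <- rep(coll_no, k)
          sp_name[[j]] <- pool$species[sp_idx]
          coll_lon[[j]] <- rep(lon, k)
          coll_lat[[j]] <- rep(lat, k)
          coll_age[[j]] <- rep(t_true, k)
          coll_h[[j]] <- stats::runif(k, 0, cfg$age_slop_frac * wc$bin_length_myr)
          coll_code[[j]] <- rep(centre$code, k)
          coll_region[[j]] <- rep(r, k)
        }
      }
      # partition the bin's collections into publication groups
      ref_of_coll <- integer(0)
      remaining <- sample(bin_coll_ids)
      while (length(remaining) > 0L) {
        ref_no <- ref_no + 1L
        g <- min(length(remaining),
                 1L + stats::rpois(1, max(0, cfg$collections_per_reference - 1)))
        ref_of_coll[as.character(remaining[seq_len(g)])] <- ref_no
        remaining <- remaining[-seq_len(g)]
      }
      if (length(coll_id)) {
        cid <- unlist(coll_id)
        age <- unlist(coll_age); h <- unlist(coll_h)
        chunks[[b]] <- data.frame(
          collection_no = cid,
          accepted_name = unlist(sp_name), accepted_rank = "species",
          paleolng = unlist(coll_lon), paleolat = unlist(coll_lat),
          max_ma = age + h, min_ma = pmax(0, age - h),
          reference_no = unname(ref_of_coll[as.character(cid)]),
          cc = unlist(coll_code),
          environment = "terrestrial indet.", group_tags = "",
          true_bin = bins$bin_id[b], true_region = unlist(coll_region))
      }
      truth_rows[[b]] <- data.frame(
        bin_id = bins$bin_id[b], window_radius_km = window_r,
        n_sampled_regions = length(sampled),
        true_pool_union = length(unique(unlist(lapply(
          world$pools[[b]][sampled], function(p) p$species)))))
    }
    occ <- if (length(chunks)) do.call(rbind, chunks) else
      data.frame(collection_no = integer(0),
                 accepted_name = character(0), accepted_rank = character(0),
                 paleolng = numeric(0), paleolat = numeric(0),
                 max_ma = numeric(0), min_ma = numeric(0),
                 reference_no = integer(0), cc = character(0),
                 environment = character(0), group_tags = character(0),
                 true_bin = character(0), true_region = integer(0))
    occ <- cbind(occurrence_no = seq_len(nrow(occ)), occ)
    if (nrow(occ) > 0L) {
      n <- nrow(occ)
      downgrade <- stats::runif(n) < cfg$frac_genus_rank
      occ$accepted_rank[downgrade] <- "genus"
      tagged <- stats::runif(n) < cfg$frac_excluded_group
      occ$group_tags[tagged] <- "Aves"
    }
    rownames(occ) <- NULL
    structure(list(
      occurrences = occ,
      truth = list(per_bin = do.call(rbind, truth_rows),
                   true_richness = world$true_richness,
                   world_seed = wc$rng_seed, sampling_seed = cfg$rng_seed)),
      class = "synthetic_record")
  })
}

#' Packaged simulation scenarios
#'
#' Fixed world/sampling configuration pairs used throughout the package's
#' validation analyses:
#' \describe{
#'   \item{flat}{Constant regional pools, full spatial coverage.}
#'   \item{constrained_shift}{Constant pools with a 2.5-fold jump at
#'     66 Ma, full coverage.}
#'   \item{expansionist}{Pools growing exponentially toward the present,
#'     full coverage.}
#'   \item{bias_demo}{Flat true diversity with an exponentially growing
#'     sampling window — the spatial-bias artefact demonstration.}
#' }
#'
#' @param name Scenario name.
#' @param seed Master seed; world and sampling seeds are derived from it.
#' @return List: `world` ([world_config()]), `sampling`
#'   ([sampling_config()]).
#' @export
make_scenario <- function(name, seed = 1L) {
  valid <- c("flat", "constrained_shift", "expansionist", "bias_demo")
  if (!name %in% valid)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  seeds <- spawn_seeds(seed, 2L)
  switch(name,
    flat = list(
      world = world_config(n_bins = 16, scenario = "flat",
                           regional_pool_size = 120, n_latent_regions = 2,
                           rng_seed = seeds[1L]),
      sampling = sampling_config(collections_per_region = 40,
                                 occurrences_per_collection = 3,
                                 rng_seed = seeds[2L])),
    constrained_shift = list(
      world = world_config(n_bins = 16, scenario = "constrained_with_shift",
                           regional_pool_size = 100, shift_factor = 2.5,
                           boundary_ma = 66, n_latent_regions = 2,
                           rng_seed = seeds[1L]),
      sampling = sampling_config(collections_per_region = 40,
                                 occurrences_per_collection = 3,
                                 rng_seed = seeds[2L])),
    expansionist = list(
      world = world_config(n_bins = 16, scenario = "expansionist",
                           regional_pool_size = 60, growth_rate = 0.012,
                           n_latent_regions = 2, rng_seed = seeds[1L]),
      sampling = sampling_config(collections_per_region = 40,
                                 occurrences_per_collection = 3,
                                 rng_seed = seeds[2L])),
    bias_demo = list(
      world = world_config(n_bins = 10, scenario = "flat",
                           regional_pool_size = 150, n_latent_regions = 6,
                           region_extent_km = 9000,
                           min_separation_km = 2500,
                           rng_seed = seeds[1L]),
      sampling = sampling_config(collections_per_region = 130,
                                 spatial_window_km = 1600,
                                 window_growth = 0.027,
                                 cluster_sd_km = 180,
                                 occurrences_per_collection = 3.5,
                                 collections_per_reference = 1.15,
                                 rng_seed = seeds[2L])))
}
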