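#' Default pipeline configuration
#'
#' @param bins Bin table ([make_time_bins()]); default contiguous 10-Myr
#'   bins over 0-160 Ma.
#' @param exclusions An [exclusion_config()].
#' @param target_mst_km Spatial scales to standardize at (km).
#' @param mst_tolerance,max_longest_branch_frac,min_references,min_multiton_ratio
#'   Standardization criteria shared across scales.
#' @param barrier_rules See [default_barrier_rules()].
#' @param quorums SQS quorum levels.
#' @param spacings Occupied-cell grid spacings (km).
#' @param gcr Optional GCR settings list (`quota_per_1000km`, `q`,
#'   `trials`); NULL disables grid-cell rarefaction.
#' @param overlap_threshold Region-cluster overlap threshold.
#' @param response_estimator Column used as the diversity response in
#'   model fits.
#' @param boundary_ma Phase boundary for model fits (Ma).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(bins = make_time_bins(160),
                            exclusions = exclusion_config(),
                            target_mst_km = c(1000, 1500, 2000, 2500,
                                              3000, 3500, 4000),
                            mst_tolerance = 0.10,
                            max_longest_branch_frac = 0.40,
                            min_references = 20,
                            min_multiton_ratio = 0.25,
                            barrier_rules = default_barrier_rules(),
                            quorums = c(0.4, 0.6, 0.8),
                            spacings = c(100, 200, 500, 1000, 5000),
                            gcr = NULL,
                            overlap_threshold = 0.25,
                            response_estimator = "sqs_q0.6",
                            boundary_ma = 66,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the spatial-standardization pipeline end to end
#'
#' Ingest, clean and bin occurrences; build spatial points on the 100-km
#' grid per bin; enumerate nested regions; characterize regions whose MST
#' length falls inside any requested spatial-scale window (regions that
#' could never survive the extent filter are skipped — a pure
#' performance measure with identical downstream results); filter to the
#' standardization criteria at each scale; apply barrier rules; cluster
#' overlapping survivors per bin; summarize clusters; and fit
#' diversification models to cluster-median diversity. Also returns the
#' global face-value/SQS/spatial-sampling time series.
#'
#' @param occurrences Occurrence CSV path or data.frame (source dialect).
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, all tables and a JSON
#'   run manifest are written there as CSV/JSON.
#' @return List of class `pipeline_result`: `global` (time series),
#'   `regions` (characterized candidates), `standardized` (per-scale
#'   filtered + clustered regions), `cluster_summaries`, `model_fits`
#'   (per scale), `manifest`.
#' @export
run_pipeline <- function(occurrences, config = pipeline_config(),
                         outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- spawn_seeds(config$seed, 4L)
  manifest <- list(seed = config$seed,
                   stage_seeds = as.list(stats::setNames(
                     seeds, c("enumerate", "characterize", "gcr", "models"))),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   package_version = as.character(
                     utils::packageVersion("palaeoreg")),
                   stages = list())

  occ <- read_occurrences(occurrences)
  manifest$stages$ingest <- attr(occ, "report")
  occ <- clean_occurrences(occ, config$exclusions)
  manifest$stages$clean <- attr(occ, "report")
  occ <- assign_time_bins(occ, config$bins)
  manifest$stages$binning <- attr(occ, "report")
  occ <- occ[!is.na(occ$bin_id), , drop = FALSE]

  global <- global_timeseries(occ, config$bins, config$quorums,
                              config$spacings)
  base_grid <- build_grid(100)
  windows <- cbind(config$target_mst_km * (1 - config$mst_tolerance),
                   config$target_mst_km * (1 + config$mst_tolerance))

  region_tabs <- list()
  bin_ids <- config$bins$bin_id[config$bins$bin_id %in% occ$bin_id]
  enum_seeds <- spawn_seeds(seeds[1L], length(bin_ids))
  char_seeds <- spawn_seeds(seeds[2L], length(bin_ids))
  n_enumerated <- 0L
  for (i in seq_along(bin_ids)) {
    b <- bin_ids[i]
    occ_b <- occ[occ$bin_id == b, , drop = FALSE]
    pts <- spatial_points(occ_b, base_grid)
    if (nrow(pts) < 2L) next
    rs <- enumerate_regions(pts, seed = enum_seeds[i])
    n_enumerated <- n_enumerated + length(rs$regions)
    in_window <- vapply(rs$regions, function(r) {
      any(r$mst_total_km >= windows[, 1L] & r$mst_total_km <= windows[, 2L])
    }, logical(1))
    if (!any(in_window)) next
    region_tabs[[b]] <- characterize_regions(
      rs$regions[in_window], pts, occ_b, bin_id = b,
      spacings = config$spacings, quorums = config$quorums,
      gcr = config$gcr, seed = char_seeds[i], base_grid = base_grid)
  }
  regions <- if (length(region_tabs)) do.call(rbind, region_tabs) else
    data.frame()
  rownames(regions) <- NULL
  manifest$stages$enumerate <- list(n_bins = length(bin_ids),
                                    n_regions_enumerated = n_enumerated,
                                    n_regions_characterized = nrow(regions))

  standardized <- list()
  cluster_summaries <- list()
  model_fits <- list()
  for (scale in config$target_mst_km) {
    crit <- standardization_criteria(
      target_mst_km = scale, mst_tolerance = config$mst_tolerance,
      max_longest_branch_frac = config$max_longest_branch_frac,
      min_references = config$min_references,
      min_multiton_ratio = config$min_multiton_ratio)
    surv <- filter_regions(regions, crit)
    surv <- apply_barrier_rules(surv, config$barrier_rules, config$bins)
    if (nrow(surv) > 0L) {
      clustered <- do.call(rbind, lapply(split(surv, surv$bin_id),
                                         cluster_regions,
                                         overlap_threshold =
                                           config$overlap_threshold))
      rownames(clustered) <- NULL
    } else clustered <- surv
    key <- sprintf("mst_%gkm", scale)
    standardized[[key]] <- clustered
    summ <- summarize_clusters(clustered)
    cluster_summaries[[key]] <- summ
    resp <- summ[summ$variable == config$response_estimator &
                   !is.na(summ$median), , drop = FALSE]
    if (nrow(resp) >= 8L) {
      mid <- stats::setNames(config$bins$midpoint_ma, config$bins$bin_id)
      model_fits[[key]] <- fit_diversity_models(
        resp$median, unname(mid[resp$bin_id]),
        boundary_ma = config$boundary_ma)
    }
    manifest$stages[[key]] <- list(n_filtered = nrow(surv),
                                   n_clusters = if (nrow(clustered))
                                     length(unique(paste(clustered$bin_id,
                                                         clustered$cluster_id)))
                                   else 0L)
  }

  result <- structure(list(global = global, regions = regions,
                           standardized = standardized,
                           cluster_summaries = cluster_summaries,
                           model_fits = model_fits, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(result, outdir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d bins, %d characterized regions, %d scales\n",
              nrow(x$global), nrow(x$regions), length(x$standardized)))
  invisible(x)
}

#' Write pipeline outputs as tidy CSV plus a JSON manifest
#'
#' @param result A `pipeline_result`.
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$global, file.path(outdir, "global_timeseries.csv"),
                   row.names = FALSE)
  if (nrow(result$regions))
    utils::write.csv(result$regions, file.path(outdir, "regions.csv"),
                     row.names = FALSE)
  for (key in names(result$standardized)) {
    if (nrow(result$standardized[[key]]))
      utils::write.csv(result$standardized[[key]],
                       file.path(outdir, sprintf("standardized_%s.csv", key)),
                       row.names = FALSE)
    if (nrow(result$cluster_summaries[[key]]))
      utils::write.csv(result$cluster_summaries[[key]],
                       file.path(outdir, sprintf("clusters_%s.csv", key)),
                       row.names = FALSE)
    if (!is.null(result$model_fits[[key]]))
      utils::write.csv(as.data.frame(result$model_fits[[key]]),
                       file.path(outdir, sprintf("models_%s.csv", key)),
                       row.names = FALSE)
  }
  jsonlite::write_json(result$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
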