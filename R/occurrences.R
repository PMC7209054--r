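#' Default PBDB column dialect
#'
#' Maps the package's canonical occurrence fields to the column names of a
#' Paleobiology Database occurrence download. Override entries to read
#' other dialects.
#'
#' @return Named character vector: canonical field -> source column name.
#' @export
pbdb_dialect <- function() {
  c(occurrence_id = "occurrence_no",
    collection_id = "collection_no",
    taxon_name    = "accepted_name",
    taxon_rank    = "accepted_rank",
    paleo_lon     = "paleolng",
    paleo_lat     = "paleolat",
    max_ma        = "max_ma",
    min_ma        = "min_ma",
    reference_id  = "reference_no",
    region_code   = "cc",
    environment   = "environment",
    group_tags    = "group_tags")
}

.mandatory_fields <- c("occurrence_id", "collection_id", "taxon_name",
                       "paleo_lon", "paleo_lat", "max_ma", "min_ma")

#' Read an occurrence table
#'
#' Reads a PBDB-style occurrence CSV, renames columns to the canonical
#' dialect, coerces types and drops rows that violate the record
#' invariants (unparseable or out-of-bounds coordinates or ages,
#' max_ma < min_ma, empty taxon names). Drop counts are attached as the
#' `"report"` attribute.
#'
#' @param path CSV file path (UTF-8, header row), or a data.frame already
#'   in the source dialect.
#' @param dialect Named map canonical field -> source column; see
#'   [pbdb_dialect()]. Fields absent from the map or file beyond the
#'   mandatory set are filled with NA.
#' @return data.frame of occurrence records in canonical columns, with
#'   attribute `report` (list of counts by drop reason).
#' @export
read_occurrences <- function(path, dialect = pbdb_dialect()) {
  raw <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (nrow(raw) == 0L) stop("empty occurrence file")
  missing_cols <- .mandatory_fields[!dialect[.mandatory_fields] %in% names(raw)]
  if (length(missing_cols))
    stop("missing mandatory column(s): ",
         paste(dialect[missing_cols], collapse = ", "))
  canon <- names(dialect)
  occ <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    matrix(nrow = nrow(raw), ncol = 0))
  for (f in canon) {
    col <- dialect[[f]]
    occ[[f]] <- if (col %in% names(raw)) raw[[col]] else NA
  }
  for (f in c("paleo_lon", "paleo_lat", "max_ma", "min_ma"))
    occ[[f]] <- suppressWarnings(as.numeric(occ[[f]]))
  occ$taxon_name <- as.character(occ$taxon_name)

  n_in <- nrow(occ)
  bad_coord <- is.na(occ$paleo_lon) | is.na(occ$paleo_lat) |
    abs(occ$paleo_lon) > 180 | abs(occ$paleo_lat) > 90
  bad_age <- is.na(occ$max_ma) | is.na(occ$min_ma) |
    occ$max_ma < occ$min_ma | occ$min_ma < 0
  bad_name <- is.na(occ$taxon_name) | !nzchar(trimws(occ$taxon_name))
  keep <- !(bad_coord | bad_age | bad_name)
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- list(
    n_read = n_in, n_kept = nrow(out), n_dropped = n_in - nrow(out),
    dropped_bad_coordinates = sum(bad_coord),
    dropped_bad_ages = sum(bad_age & !bad_coord),
    dropped_empty_taxon = sum(bad_name & !bad_coord & !bad_age))
  out
}

#' Default cleaning configuration
#'
#' Species-level analysis of non-flying, non-marine taxa: excludes the
#' flying tetrapod groups (whose record is inadequate in most intervals
#' and Lagerstaetten-dominated) and common marine environment strings, and
#' keeps species/subspecies-rank identifications only. All sets are plain
#' configuration; the engine is taxon-agnostic.
#'
#' @param excluded_group_tags Higher-taxon labels to exclude.
#' @param excluded_environments Environment strings to exclude.
#' @param allowed_ranks Accepted taxon ranks.
#' @param drop_missing_paleocoords Drop records without palaeocoordinates
#'   (already enforced at read time; kept for explicitness).
#' @return List of class `exclusion_config`.
#' @export
exclusion_config <- function(
    excluded_group_tags = c("Aves", "Pterosauromorpha", "Chiroptera"),
    excluded_environments = c("marine indet.", "open shallow subtidal",
                              "offshore", "deep-water indet.", "reef",
                              "basinal (carbonate)", "basinal (siliceous)"),
    allowed_ranks = c("species", "subspecies"),
    drop_missing_paleocoords = TRUE) {
  structure(list(excluded_group_tags = excluded_group_tags,
                 excluded_environments = excluded_environments,
                 allowed_ranks = allowed_ranks,
                 drop_missing_paleocoords = drop_missing_paleocoords),
            class = "exclusion_config")
}

#' Clean an occurrence table
#'
#' Removes records whose group tags intersect the excluded set, whose
#' environment is excluded, or whose rank is not allowed. Removal tallies
#' per rule are attached as the `"report"` attribute. Idempotent.
#'
#' @param occurrences data.frame from [read_occurrences()].
#' @param config An [exclusion_config()].
#' @return Surviving records, with attribute `report`.
#' @export
clean_occurrences <- function(occurrences, config = exclusion_config()) {
  n_in <- nrow(occurrences)
  tags <- occurrences$group_tags %||% rep(NA_character_, n_in)
  hit_tag <- if (length(config$excluded_group_tags)) {
    vapply(strsplit(ifelse(is.na(tags), "", as.character(tags)), "[;,|]\\s*"),
           function(tg) any(trimws(tg) %in% config$excluded_group_tags),
           logical(1))
  } else rep(FALSE, n_in)
  env <- occurrences$environment %||% rep(NA_character_, n_in)
  hit_env <- if (length(config$excluded_environments)) {
    !is.na(env) & trimws(as.character(env)) %in% config$excluded_environments
  } else rep(FALSE, n_in)
  rank <- occurrences$taxon_rank %||% rep(NA_character_, n_in)
  hit_rank <- if (length(config$allowed_ranks)) {
    !(as.character(rank) %in% config$allowed_ranks)
  } else rep(FALSE, n_in)
  keep <- !(hit_tag | hit_env | hit_rank)
  out <- occurrences[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no occurrences survived cleaning")
  attr(out, "report") <- list(
    n_in = n_in, n_kept = nrow(out),
    removed_excluded_group = sum(hit_tag),
    removed_excluded_environment = sum(hit_env & !hit_tag),
    removed_rank = sum(hit_rank & !hit_tag & !hit_env))
  out
}

#' Build a table of contiguous equal-length time bins
#'
#' @param oldest_ma Older bound of the oldest bin (Ma).
#' @param youngest_ma Younger bound of the youngest bin (Ma).
#' @param bin_length_myr Bin length in Myr (default 10).
#' @return data.frame `bin_id`, `early_ma`, `late_ma`, `midpoint_ma`,
#'   ordered old to young.
#' @export
make_time_bins <- function(oldest_ma, youngest_ma = 0, bin_length_myr = 10) {
  stopifnot(oldest_ma > youngest_ma, bin_length_myr > 0)
  early <- seq(oldest_ma, youngest_ma + bin_length_myr, by = -bin_length_myr)
  late <- early - bin_length_myr
  data.frame(bin_id = sprintf("bin_%03.0f_%03.0f", early, late),
             early_ma = early, late_ma = late,
             midpoint_ma = (early + late) / 2)
}

#' Assign occurrences to time bins
#'
#' An occurrence is assigned to the unique bin covering strictly more than
#' 50% of its [min_ma, max_ma] age range. Zero-length ranges go to the bin
#' containing the point age; a point sitting exactly on a bin boundary
#' goes to the older bin (geologic boundary-age convention). Occurrences
#' with no qualifying bin get `bin_id` NA and are counted in the report.
#'
#' @param occurrences data.frame with `min_ma`, `max_ma`.
#' @param bins Bin table from [make_time_bins()] (non-overlapping, ordered).
#' @return `occurrences` with a `bin_id` column added; attribute `report`
#'   holds the dropped count.
#' @export
assign_time_bins <- function(occurrences, bins) {
  stopifnot(all(bins$early_ma > bins$late_ma))
  n <- nrow(occurrences)
  bin_id <- rep(NA_character_, n)
  len <- occurrences$max_ma - occurrences$min_ma
  for (i in seq_len(nrow(bins))) {
    e <- bins$early_ma[i]; l <- bins$late_ma[i]
    ov <- pmin(occurrences$max_ma, e) - pmax(occurrences$min_ma, l)
    hit <- len > 0 & ov / len > 0.5
    # point ages: bin interval is [late, early), except the oldest bin
    # which includes its early bound
    pt <- len == 0 &
      occurrences$min_ma >= l &
      (occurrences$min_ma < e | (i == 1L & occurrences$min_ma == e))
    bin_id[(hit | pt) & is.na(bin_id)] <- bins$bin_id[i]
  }
  out <- occurrences
  out$bin_id <- bin_id
  attr(out, "report") <- list(n_in = n, n_binned = sum(!is.na(bin_id)),
                              n_dropped = sum(is.na(bin_id)))
  out
}
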