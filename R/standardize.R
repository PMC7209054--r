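#' Spatial-standardization criteria
#'
#' A region survives standardization when, simultaneously: its MST total
#' length lies within `target_mst_km` +/- `mst_tolerance`; its longest MST
#' branch is at most `max_longest_branch_frac` of the total (excluding
#' widely separated cluster pairs); it is reported by at least
#' `min_references` literature references (a minimum level of study); and
#' its multiton ratio is at least `min_multiton_ratio` (a minimum level of
#' sample completeness).
#'
#' @param target_mst_km Target MST length (km); the standard scales are
#'   1000, 1500, 2000, 2500, 3000, 3500 and 4000 km.
#' @param mst_tolerance Fractional tolerance around the target (default
#'   0.10).
#' @param max_longest_branch_frac Maximum longest-branch/total fraction
#'   (default 0.40).
#' @param min_references Minimum distinct references (default 20).
#' @param min_multiton_ratio Minimum multiton ratio (default 0.25).
#' @return List of class `standardization_criteria`.
#' @export
standardization_criteria <- function(target_mst_km,
                                     mst_tolerance = 0.10,
                                     max_longest_branch_frac = 0.40,
                                     min_references = 20,
                                     min_multiton_ratio = 0.25) {
  stopifnot(target_mst_km > 0, mst_tolerance > 0, mst_tolerance < 1,
            max_longest_branch_frac > 0, max_longest_branch_frac <= 1)
  structure(list(target_mst_km = target_mst_km,
                 mst_tolerance = mst_tolerance,
                 max_longest_branch_frac = max_longest_branch_frac,
                 min_references = min_references,
                 min_multiton_ratio = min_multiton_ratio),
            class = "standardization_criteria")
}

#' Filter characterized regions to standardization criteria
#'
#' @param regions data.frame from [characterize_regions()].
#' @param criteria A [standardization_criteria()].
#' @return The surviving rows. All four criteria are conjunctive;
#'   idempotent, and monotone (stricter criteria keep a subset).
#' @export
filter_regions <- function(regions, criteria) {
  stopifnot(inherits(criteria, "standardization_criteria"))
  if (nrow(regions) == 0L) return(regions)
  lo <- criteria$target_mst_km * (1 - criteria$mst_tolerance)
  hi <- criteria$target_mst_km * (1 + criteria$mst_tolerance)
  frac <- ifelse(regions$mst_total_km > 0,
                 regions$mst_longest_km / regions$mst_total_km, 0)
  keep <- regions$mst_total_km >= lo & regions$mst_total_km <= hi &
    frac <= criteria$max_longest_branch_frac &
    !is.na(regions$n_references) &
    regions$n_references >= criteria$min_references &
    !is.na(regions$multiton_ratio) &
    regions$multiton_ratio >= criteria$min_multiton_ratio
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default palaeogeographical barrier rules
#'
#' Region-code pairs that become separated by oceanic barriers: South
#' America and Africa after 120 Ma, Australia and New Zealand after
#' 70 Ma, Europe and Africa after 66 Ma. Codes follow the continental
#' region labels used elsewhere in the package ("SA", "AF", "AUS", "NZ",
#' "EU"); supply your own rules for country-level codes.
#'
#' @return List of rules; each has `side_a`, `side_b` (character vectors
#'   of region codes) and `active_after_ma`.
#' @export
default_barrier_rules <- function() {
  list(list(side_a = "SA",  side_b = "AF", active_after_ma = 120),
       list(side_a = "AUS", side_b = "NZ", active_after_ma = 70),
       list(side_a = "EU",  side_b = "AF", active_after_ma = 66))
}

#' Remove regions that span geographic barriers
#'
#' A region is removed when its bin midpoint is younger than a rule's
#' activation age and its member collections include region codes from
#' both sides of that rule.
#'
#' @param regions Characterized regions (needs `region_codes`).
#' @param rules List of barrier rules; see [default_barrier_rules()].
#' @param bin_midpoints Named vector bin_id -> midpoint age (Ma), or a bin
#'   table from [make_time_bins()].
#' @return The surviving rows.
#' @export
apply_barrier_rules <- function(regions, rules = default_barrier_rules(),
                                bin_midpoints) {
  if (nrow(regions) == 0L || length(rules) == 0L) return(regions)
  if (is.data.frame(bin_midpoints))
    bin_midpoints <- stats::setNames(bin_midpoints$midpoint_ma,
                                     bin_midpoints$bin_id)
  mid <- bin_midpoints[regions$bin_id]
  codes <- strsplit(ifelse(is.na(regions$region_codes), "",
                           regions$region_codes), " +")
  crossed <- rep(FALSE, nrow(regions))
  for (r in rules) {
    active <- !is.na(mid) & mid < r$active_after_ma
    hits <- vapply(codes, function(cc)
      any(cc %in% r$side_a) && any(cc %in% r$side_b), logical(1))
    crossed <- crossed | (active & hits)
  }
  out <- regions[!crossed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster overlapping regions
#'
#' Groups surviving regions of one bin into clusters of mutually
#' overlapping regions: two regions are linked when they share more than
#' `overlap_threshold` of the spatial points of the smaller one, and
#' clusters are the connected components of that link relation
#' (single-linkage transitive closure, so the result is a partition and
#' is invariant to input order). Cluster ids are assigned by processing
#' regions in descending member count, ties by the lexicographic member
#' key, which makes labels deterministic too.
#'
#' @param regions Characterized regions data.frame (needs `members`).
#' @param overlap_threshold Shared fraction above which regions are linked
#'   (default 0.25).
#' @return `regions` with a `cluster_id` column added.
#' @export
cluster_regions <- function(regions, overlap_threshold = 0.25) {
  n <- nrow(regions)
  if (n == 0L) {
    regions$cluster_id <- integer(0)
    return(regions)
  }
  members <- lapply(strsplit(regions$members, " +"), as.integer)
  sizes <- lengths(members)
  # union-find over the overlap graph; overlap(A,B) = |A n B| / min(|A|,|B|)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      ma <- members[[a]]
      for (b in (a + 1L):n) {
        ov <- length(intersect(ma, members[[b]])) / min(sizes[a], sizes[b])
        if (ov > overlap_threshold) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[rb] <- ra
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # deterministic labels: clusters numbered by their first region under
  # descending-size, lexicographic-key order
  ord <- order(-sizes, regions$members)
  nxt <- 0L
  cluster_of_root <- integer(0)
  cl <- integer(n)
  for (i in ord) {
    r <- as.character(root[i])
    if (is.na(match(r, names(cluster_of_root)))) {
      nxt <- nxt + 1L
      cluster_of_root[r] <- nxt
    }
    cl[i] <- cluster_of_root[[r]]
  }
  regions$cluster_id <- cl
  regions
}

#' Summarize region clusters
#'
#' Per cluster and per variable: the median and interquartile range over
#' member regions (linear-interpolation quartiles, missing values
#' ignored), the number of contributing regions, and the modal dominant
#' region code.
#'
#' @param regions Clustered regions from [cluster_regions()].
#' @param variables Character vector of numeric columns to summarize.
#' @return Tidy data.frame: `bin_id`, `cluster_id`, `variable`, `median`,
#'   `iqr`, `n_regions`, `dominant_region_code`.
#' @export
summarize_clusters <- function(regions,
                               variables = c("mst_total_km", "n_occurrences",
                                             "n_references", "face_value",
                                             "sqs_q0.4", "sqs_q0.6", "sqs_q0.8",
                                             "chao2", "squares")) {
  variables <- intersect(variables, names(regions))
  out <- list()
  if (nrow(regions) == 0L)
    return(data.frame(bin_id = character(0), cluster_id = integer(0),
                      variable = character(0), median = numeric(0),
                      iqr = numeric(0), n_regions = integer(0),
                      dominant_region_code = character(0)))
  for (key in unique(paste(regions$bin_id, regions$cluster_id))) {
    sub <- regions[paste(regions$bin_id, regions$cluster_id) == key, ,
                   drop = FALSE]
    dom <- if ("dominant_region_code" %in% names(sub))
      modal_value(sub$dominant_region_code) else NA_character_
    for (v in variables) {
      x <- sub[[v]]
      x <- x[!is.na(x)]
      out[[length(out) + 1L]] <- data.frame(
        bin_id = sub$bin_id[1L], cluster_id = sub$cluster_id[1L],
        variable = v,
        median = if (length(x)) stats::median(x) else NA_real_,
        iqr = if (length(x)) stats::IQR(x, type = 7) else NA_real_,
        n_regions = length(x),
        dominant_region_code = dom)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
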