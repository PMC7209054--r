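#' Great-circle distance in kilometres
#'
#' Haversine distance on a spherical Earth (radius 6371.0088 km, the IUGG
#' mean radius). Palaeocoordinate uncertainty dwarfs the spherical vs
#' ellipsoidal difference, so no ellipsoid correction is attempted.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees. Vectors are
#'   recycled in the usual way.
#' @return Distance(s) in km.
#' @export
#' @examples
#' great_circle_km(0, 0, 0, 1) # one degree of latitude, ~111.195 km
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(abs(lat1) <= 90, na.rm = TRUE), all(abs(lat2) <= 90, na.rm = TRUE),
            all(abs(lon1) <= 180, na.rm = TRUE), all(abs(lon2) <= 180, na.rm = TRUE))
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  a <- pmin(1, pmax(0, a))
  2 * r * asin(sqrt(a))
}

#' Pairwise great-circle distance matrix
#'
#' @param lon,lat Coordinate vectors in decimal degrees.
#' @return A dense symmetric matrix of distances in km.
#' @export
great_circle_matrix <- function(lon, lat) {
  n <- length(lon)
  stopifnot(length(lat) == n)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  D <- matrix(0, n, n)
  if (n > 1L) {
    idx <- seq_len(n)
    for (i in idx[-n]) {
      j <- (i + 1L):n
      d <- great_circle_km(lon[i], lat[i], lon[j], lat[j])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Minimum spanning tree over points on the sphere
#'
#' Computes the MST of the complete great-circle-distance graph on a point
#' set by Prim's algorithm. Total MST length is the measure of
#' palaeogeographical spread used throughout the pipeline; the longest
#' single branch flags regions made of widely separated clusters.
#'
#' @param lon,lat Point coordinates in decimal degrees (one point per
#'   element), or `lon` may be a precomputed symmetric distance matrix in
#'   which case `lat` is ignored.
#' @return A list of class `mst_result` with elements `total_km`,
#'   `longest_km`, and `edges` (data.frame `from`, `to`, `km`; point indices
#'   refer to input order).
#' @export
minimum_spanning_tree <- function(lon, lat = NULL) {
  if (is.matrix(lon)) {
    D <- lon
    n <- nrow(D)
  } else {
    n <- length(lon)
    D <- great_circle_matrix(lon, lat)
  }
  if (n < 1L) stop("minimum_spanning_tree() needs at least one point")
  edges <- data.frame(from = integer(0), to = integer(0), km = numeric(0))
  if (n == 1L) {
    return(structure(list(total_km = 0, longest_km = 0, edges = edges),
                     class = "mst_result"))
  }
  # Prim with O(n^2) dense update
  in_tree <- rep(FALSE, n)
  in_tree[1L] <- TRUE
  best_d <- D[1L, ]
  best_from <- rep(1L, n)
  best_d[1L] <- Inf
  from <- to <- integer(n - 1L)
  km <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    j <- which.min(best_d)
    from[k] <- best_from[j]
    to[k] <- j
    km[k] <- best_d[j]
    in_tree[j] <- TRUE
    upd <- !in_tree & D[j, ] < best_d
    best_d[upd] <- D[j, upd]
    best_from[upd] <- j
    best_d[j] <- Inf
  }
  structure(list(total_km = sum(km), longest_km = max(km),
                 edges = data.frame(from = from, to = to, km = km)),
            class = "mst_result")
}

#' @export
print.mst_result <- function(x, ...) {
  cat(sprintf("MST: %d edges, total %.1f km, longest branch %.1f km\n",
              nrow(x$edges), x$total_km, x$longest_km))
  invisible(x)
}
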