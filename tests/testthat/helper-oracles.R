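# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive: enumeration and resampling, no shared code paths
# with the implementations they check.

# Monte-Carlo rarefaction oracle. For a frequency vector and subsample
# size m (< n), estimates by permutation:
#  - expected subsample species richness, and
#  - expected coverage, via the identity that the coverage deficit equals
#    the probability that the (m+1)-th occurrence of a random permutation
#    belongs to a species absent from the first m.
mc_rarefaction_oracle <- function(counts, m, reps = 20000) {
  labels <- rep.int(seq_along(counts), counts)
  n <- length(labels)
  stopifnot(m >= 1, m < n)
  s <- integer(reps)
  new_draw <- logical(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, m + 1L)
    first <- labels[idx[seq_len(m)]]
    s[r] <- length(unique(first))
    new_draw[r] <- !(labels[idx[m + 1L]] %in% first)
  }
  # SE floored at the resolution of the simulation (1/reps): a quantity
  # whose estimator was constant across reps still cannot be resolved
  # more finely than one event in `reps`
  list(richness = mean(s),
       richness_se = max(stats::sd(s) / sqrt(reps), 1 / reps),
       coverage = 1 - mean(new_draw),
       coverage_se = max(stats::sd(new_draw) / sqrt(reps), 1 / reps))
}

# brute-force MST total length: enumerate all labelled spanning trees on
# n nodes through Prufer sequences (n^(n-2) trees) and take the minimum
mst_bruteforce_total <- function(D) {
  n <- nrow(D)
  if (n == 1L) return(0)
  if (n == 2L) return(D[1L, 2L])
  decode_weight <- function(code) {
    degree <- tabulate(code, n) + 1L
    total <- 0
    for (v in code) {
      leaf <- which.max(degree == 1L) # lowest-numbered leaf
      total <- total + D[leaf, v]
      degree[leaf] <- 0L
      degree[v] <- degree[v] - 1L
    }
    ends <- which(degree == 1L)
    total + D[ends[1L], ends[2L]]
  }
  codes <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  min(apply(codes, 1L, decode_weight))
}

# exhaustive region-enumeration oracle: replay the nearest-point growth
# rule from every start, branching over every tie ordering, and collect
# the distinct member sets of size >= 2 (as sorted index keys)
region_enumeration_oracle <- function(D, tol = 1e-9) {
  n <- nrow(D)
  found <- new.env(hash = TRUE, parent = emptyenv())
  recurse <- function(set) {
    if (length(set) >= 2L)
      found[[paste(sort.int(set), collapse = " ")]] <- TRUE
    if (length(set) == n) return(invisible())
    rest <- setdiff(seq_len(n), set)
    d <- vapply(rest, function(j) min(D[j, set]), numeric(1))
    for (j in rest[d <= min(d) + tol]) recurse(c(set, j))
  }
  for (s in seq_len(n)) recurse(s)
  sort(names(as.list(found)))
}

# random lon/lat point sets in a compact patch (keeps distances generic)
random_point_set <- function(n, lon_range = c(-40, 40), lat_range = c(-30, 30)) {
  data.frame(cell_id = seq_len(n),
             lon = stats::runif(n, lon_range[1], lon_range[2]),
             lat = stats::runif(n, lat_range[1], lat_range[2]))
}

# minimal characterized-region table for filter/cluster algebra tests
random_region_table <- function(n, n_cells = 12) {
  data.frame(
    bin_id = "b1",
    members = vapply(seq_len(n), function(i)
      paste(sort(sample.int(n_cells, sample(2:6, 1))), collapse = " "),
      character(1)),
    mst_total_km = stats::runif(n, 500, 4500),
    mst_longest_km = NA_real_,
    n_references = sample(5:40, n, replace = TRUE),
    multiton_ratio = stats::runif(n),
    stringsAsFactors = FALSE
  ) -> tab
  tab$mst_longest_km <- tab$mst_total_km * stats::runif(n, 0.1, 0.6)
  tab
}
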