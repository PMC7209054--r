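#' Species frequency vector from taxon names
#'
#' @param taxa Character vector of taxon names, one element per occurrence.
#' @return Named integer vector of per-species occurrence counts.
#' @export
frequency_vector <- function(taxa) {
  taxa <- taxa[!is.na(taxa) & nzchar(taxa)]
  tab <- table(taxa)
  stats::setNames(as.integer(tab), names(tab))
}

#' Frequency-based coverage statistics
#'
#' Good's u (1 - f1/n), the multiton ratio ((S_obs - f1)/S_obs; the
#' proportion of observed species seen more than once — a conservative
#' completeness screen), and the analytic estimated coverage of the
#' reference sample used by coverage-based rarefaction:
#' \deqn{\hat C = 1 - (f_1/n)\,\frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}}
#' with \eqn{\hat C = 1} when there are no singletons.
#'
#' @param counts Positive integer vector of per-species occurrence counts.
#' @return List: `goods_u`, `multiton_ratio`, `coverage`, plus `n`,
#'   `s_obs`, `f1`, `f2`.
#' @export
coverage_stats <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || sum(counts) < 1) stop("empty frequency vector")
  stopifnot(all(counts >= 1), all(counts == round(counts)))
  n <- sum(counts)
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  denom <- (n - 1) * f1 + 2 * f2
  cov <- if (f1 == 0) 1 else if (denom == 0) 1 - f1 / n else
    1 - (f1 / n) * ((n - 1) * f1 / denom)
  list(goods_u = 1 - f1 / n,
       multiton_ratio = (s_obs - f1) / s_obs,
       coverage = cov,
       n = n, s_obs = s_obs, f1 = f1, f2 = f2)
}

# expected species richness in a without-replacement subsample of size m
# (vectorized over m): S_obs - sum_i C(n - X_i, m)/C(n, m)
rarefied_richness <- function(counts, m) {
  n <- sum(counts)
  stopifnot(all(m >= 0), all(m <= n))
  vapply(m, function(mm) {
    length(counts) - sum(exp(lchoose(n - counts, mm) - lchoose(n, mm)))
  }, numeric(1))
}

# expected coverage of a without-replacement subsample of size m < n:
# 1 - sum_i (X_i/n) C(n - X_i, m)/C(n - 1, m). Equivalently one minus the
# probability that the (m+1)-th occurrence of a random permutation belongs
# to a species absent from the first m. At m = n the reference-sample
# estimate of coverage_stats() is used.
rarefied_coverage <- function(counts, m) {
  n <- sum(counts)
  stopifnot(all(m >= 0), all(m <= n))
  ref <- coverage_stats(counts)$coverage
  vapply(m, function(mm) {
    if (mm >= n) return(ref)
    1 - sum((counts / n) * exp(lchoose(n - counts, mm) - lchoose(n - 1, mm)))
  }, numeric(1))
}

# estimated number of undetected species (Chao1-type f0-hat)
.f0_hat <- function(n, f1, f2) {
  if (f1 == 0) return(0)
  if (f2 > 0) ((n - 1) / n) * f1^2 / (2 * f2)
  else ((n - 1) / n) * f1 * (f1 - 1) / 2
}

#' Coverage-standardized species richness (SQS)
#'
#' Shareholder quorum subsampling / coverage-based rarefaction by the
#' analytic route: the expected richness of the sample size at which
#' estimated coverage equals the quorum `q`. Sizes below the reference
#' sample use the hypergeometric interpolation formulas; sizes above use
#' the standard extrapolation
#' \deqn{\hat S(n+m^*) = S_{obs} + \hat f_0 [1 - (1 - f_1/(n \hat f_0 + f_1))^{m^*}]}
#' with coverage extrapolated as
#' \eqn{1 - (f_1/n) [(n-1) f_1 / ((n-1) f_1 + 2 f_2)]^{m^*+1}}.
#' Fractional target sizes are resolved by linear interpolation between
#' adjacent integer sizes (interpolation side) or by the continuous
#' extrapolation formula (extrapolation side).
#'
#' @param counts Per-species occurrence counts (positive integers).
#' @param q Quorum: target coverage in (0, 1).
#' @return List of class `richness_estimate`: `estimator` ("sqs"),
#'   `value` (species; NA when undefined), `params` (q, target size),
#'   `flags` (character; may include `"extrapolated_beyond_2n"`,
#'   `"undefined_fallback"`).
#' @export
sqs_richness <- function(counts, q) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("quorum q must be a single number in (0, 1)")
  counts <- as.numeric(counts[counts > 0])
  if (length(counts) == 0L || sum(counts) < 1) stop("empty frequency vector")
  n <- sum(counts)
  s_obs <- length(counts)
  if (s_obs == 1L) {
    # one observed species: standardized richness is 1 at any quorum
    return(structure(list(estimator = "sqs", value = 1,
                          params = list(q = q, m_target = 1),
                          flags = character(0)),
                     class = "richness_estimate"))
  }
  cs <- coverage_stats(counts)
  flags <- character(0)

  if (q <= cs$coverage + 1e-12) {
    # interpolation (or the observed point itself)
    if (abs(q - cs$coverage) <= 1e-12) {
      value <- s_obs
      m_target <- n
    } else {
      mm <- seq_len(n) # smallest meaningful sample is one occurrence
      cov <- rarefied_coverage(counts, mm)
      # coverage is non-decreasing in m; find bracketing integers
      hi <- which(cov >= q - 1e-12)[1L]
      if (is.na(hi)) hi <- n
      if (hi <= 1L) {
        m_target <- 1
        value <- rarefied_richness(counts, 1)
      } else {
        lo <- hi - 1L
        c_lo <- cov[lo]; c_hi <- cov[hi]
        w <- if (c_hi > c_lo) (q - c_lo) / (c_hi - c_lo) else 0
        s_lo <- rarefied_richness(counts, mm[lo])
        s_hi <- rarefied_richness(counts, mm[hi])
        value <- s_lo + w * (s_hi - s_lo)
        m_target <- mm[lo] + w
      }
    }
  } else {
    # extrapolation
    f1 <- cs$f1; f2 <- cs$f2
    f0 <- .f0_hat(n, f1, f2)
    if (f1 >= n || f0 == 0) {
      return(structure(list(estimator = "sqs", value = NA_real_,
                            params = list(q = q, m_target = NA_real_),
                            flags = "undefined_fallback"),
                       class = "richness_estimate"))
    }
    b <- (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
    if (b <= 0 || b >= 1) {
      return(structure(list(estimator = "sqs", value = NA_real_,
                            params = list(q = q, m_target = NA_real_),
                            flags = "undefined_fallback"),
                       class = "richness_estimate"))
    }
    # solve 1 - (f1/n) b^(m'+1) = q for continuous m'
    mprime <- log((1 - q) * n / f1) / log(b) - 1
    mprime <- max(0, mprime)
    value <- s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^mprime)
    m_target <- n + mprime
    if (m_target > 2 * n) flags <- c(flags, "extrapolated_beyond_2n")
  }
  structure(list(estimator = "sqs", value = value,
                 params = list(q = q, m_target = m_target), flags = flags),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("%s richness estimate: %s%s\n", x$estimator,
              format(x$value),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Chao 2 incidence-based richness extrapolator
#'
#' Classical Chao 2 \eqn{\hat S = S_{obs} + \frac{m-1}{m}\frac{q_1^2}{2 q_2}}
#' when doubletons are present, switching to the bias-corrected form
#' \eqn{S_{obs} + \frac{m-1}{m}\frac{q_1 (q_1 - 1)}{2}} (flagged) when
#' \eqn{q_2 = 0}. Sampling units default to collections.
#'
#' @param unit_counts Integer vector: for each observed species, the number
#'   of sampling units (collections) it occurs in.
#' @param m Number of sampling units.
#' @return A `richness_estimate` (estimator "chao2").
#' @export
chao2 <- function(unit_counts, m) {
  stopifnot(m >= 1, all(unit_counts >= 1), all(unit_counts <= m))
  s_obs <- length(unit_counts)
  q1 <- sum(unit_counts == 1)
  q2 <- sum(unit_counts == 2)
  flags <- character(0)
  add <- if (q2 > 0) {
    ((m - 1) / m) * q1^2 / (2 * q2)
  } else {
    flags <- "bias_corrected_q2_zero"
    ((m - 1) / m) * q1 * (q1 - 1) / 2
  }
  structure(list(estimator = "chao2", value = s_obs + add,
                 params = list(m = m, q1 = q1, q2 = q2), flags = flags),
            class = "richness_estimate")
}

#' Squares richness extrapolator
#'
#' Frequency-based asymptotic estimator
#' \deqn{\hat S = S_{obs} + \frac{f_1^2 \sum_i X_i^2}{n^2 - f_1 S_{obs}}.}
#' Undefined (NA, flagged) when every species is a singleton.
#'
#' @param counts Per-species occurrence counts.
#' @return A `richness_estimate` (estimator "squares").
#' @export
squares_richness <- function(counts) {
  counts <- as.numeric(counts[counts > 0])
  if (length(counts) == 0L) stop("empty frequency vector")
  n <- sum(counts)
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  denom <- n^2 - f1 * s_obs
  if (f1 == s_obs && n == s_obs) {
    return(structure(list(estimator = "squares", value = NA_real_,
                          params = list(), flags = "undefined_fallback"),
                     class = "richness_estimate"))
  }
  structure(list(estimator = "squares",
                 value = s_obs + f1^2 * sum(counts^2) / denom,
                 params = list(), flags = character(0)),
            class = "richness_estimate")
}

#' Grid-cell rarefied SQS
#'
#' Controls for variable packing density of localities inside equal-extent
#' regions: occupied 200-km cells are subsampled down to a quota
#' proportional to the region's MST length
#' (`round(quota_per_1000km * mst_total_km / 1000)`), occurrences of the
#' drawn cells are pooled, SQS is computed, and the estimate is averaged
#' over `trials` random draws. Regions with fewer occupied cells than the
#' quota return NA.
#'
#' @param occurrences The region's occurrences (needs `taxon_name`,
#'   `paleo_lon`, `paleo_lat`).
#' @param mst_total_km Region MST total length (km).
#' @param q SQS quorum.
#' @param quota_per_1000km Cells per 1000 km of MST (3, 5 or 8 in the
#'   standard configuration).
#' @param cell_spacing_km Rarefaction grid spacing (default 200).
#' @param trials Number of subsampling trials (default 50).
#' @param seed RNG seed for reproducible draws.
#' @return A `richness_estimate` (estimator "sqs_gcr"); value is the
#'   trial-mean SQS richness.
#' @export
gcr_sqs <- function(occurrences, mst_total_km, q, quota_per_1000km,
                    cell_spacing_km = 200, trials = 50, seed = NULL) {
  stopifnot(quota_per_1000km > 0, trials >= 1)
  quota <- round(quota_per_1000km * mst_total_km / 1000)
  grid <- build_grid(cell_spacing_km)
  cid <- assign_cell(grid, occurrences$paleo_lon, occurrences$paleo_lat)
  cells <- unique(cid)
  if (length(cells) < quota || quota < 1) {
    return(structure(list(estimator = "sqs_gcr", value = NA_real_,
                          params = list(q = q, quota = quota,
                                        n_cells = length(cells)),
                          flags = "below_quota"),
                     class = "richness_estimate"))
  }
  vals <- with_seed(seed, vapply(seq_len(trials), function(i) {
    drawn <- sample(cells, quota)
    est <- sqs_richness(frequency_vector(occurrences$taxon_name[cid %in% drawn]), q)
    est$value
  }, numeric(1)))
  structure(list(estimator = "sqs_gcr", value = mean(vals, na.rm = TRUE),
                 params = list(q = q, quota = quota, trials = trials,
                               n_cells = length(cells),
                               n_failed_trials = sum(is.na(vals))),
                 flags = character(0)),
            class = "richness_estimate")
}
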