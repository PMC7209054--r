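#' Global per-bin diversity and spatial-sampling time series
#'
#' Face-value worldwide species counts, SQS richness of the pooled global
#' frequency vector at each quorum, and occupied equal-area cell counts at
#' each spacing, per time bin. This is the "global" curve whose trend is
#' confounded with spatial sampling; it is the input to the
#' first-difference bias regressions.
#'
#' @param occurrences Binned occurrences (needs `bin_id`, `taxon_name`,
#'   `paleo_lon`, `paleo_lat`).
#' @param bins Bin table from [make_time_bins()].
#' @param quorums SQS quorum levels.
#' @param spacings Grid spacings (km).
#' @return data.frame, one row per bin, old to young.
#' @export
global_timeseries <- function(occurrences, bins,
                              quorums = c(0.4, 0.6, 0.8),
                              spacings = c(100, 200, 500, 1000, 5000)) {
  grids <- lapply(spacings, build_grid)
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    b <- bins$bin_id[i]
    occ <- occurrences[!is.na(occurrences$bin_id) & occurrences$bin_id == b, ,
                       drop = FALSE]
    row <- data.frame(bin_id = b, midpoint_ma = bins$midpoint_ma[i],
                      n_occurrences = nrow(occ),
                      n_collections = length(unique(occ$collection_id)))
    if (nrow(occ) > 0L) {
      freq <- frequency_vector(occ$taxon_name)
      row$face_value <- length(freq)
      for (q in quorums)
        row[[sprintf("sqs_q%g", q)]] <-
          tryCatch(sqs_richness(freq, q)$value, error = function(e) NA_real_)
    } else {
      row$face_value <- 0L
      for (q in quorums) row[[sprintf("sqs_q%g", q)]] <- NA_real_
    }
    for (j in seq_along(spacings))
      row[[sprintf("cells_%gkm", spacings[j])]] <-
        count_occupied_cells(occ, grids[[j]])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' First-difference regression between two time series
#'
#' Ordinary least squares of bin-to-bin changes in `y` on bin-to-bin
#' changes in `x` (both log-transformed by default), the standard
#' detrended test of whether changes in apparent diversity track changes
#' in a sampling proxy. Bins with missing values in either series are
#' dropped pairwise before differencing; outlier bins can be excluded by
#' id.
#'
#' @param y,x Numeric series aligned on the same bins, old to young.
#' @param bin_ids Optional bin labels (needed for `exclude`).
#' @param log_transform Log both series before differencing (default
#'   TRUE; requires positive values).
#' @param exclude Bin ids to drop before differencing.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n_diffs`.
#' @export
first_difference_fit <- function(y, x, bin_ids = NULL, log_transform = TRUE,
                                 exclude = NULL) {
  stopifnot(length(y) == length(x))
  keep <- !(is.na(y) | is.na(x))
  if (!is.null(exclude) && !is.null(bin_ids))
    keep <- keep & !(bin_ids %in% exclude)
  y <- y[keep]; x <- x[keep]
  if (log_transform) {
    if (any(y <= 0) || any(x <= 0))
      stop("log transform requires strictly positive values")
    y <- log(y); x <- log(x)
  }
  dy <- diff(y); dx <- diff(x)
  if (length(dy) < 4L) stop("fewer than 4 paired first differences")
  fit <- stats::lm(dy ~ dx)
  # summary.lm warns on exact fits (e.g. y proportional to x); that is a
  # valid input here, not a problem
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  if (is.nan(r2)) r2 <- 0 # constant response: nothing to explain
  p <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2L, 4L] else NA_real_
  slope <- if (length(stats::coef(fit)) >= 2L && !is.na(stats::coef(fit)[2L]))
    unname(stats::coef(fit)[2L]) else 0
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       p_value = p,
       n_diffs = length(dy))
}

#' Compare diversification models by AICc
#'
#' Fits the five-member least-squares model lattice for log richness as a
#' function of time and a diversification phase that switches at the K/Pg
#' boundary: intercept only (static diversity), time (continuous
#' expansion), time + phase (parallel equilibria), time x phase
#' (equilibria with phase-specific trends) and phase only (pure step).
#' Models are ranked by AICc computed with the least-squares convention
#' \eqn{AICc = n \ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)}, where `k` counts the
#' residual variance as a parameter.
#'
#' @param richness Richness values (one per data point, e.g. cluster
#'   medians); log-transformed internally.
#' @param midpoint_ma Age of each data point (Ma).
#' @param boundary_ma Phase boundary (default 66, the K/Pg).
#' @param log_transform Log the response (default TRUE).
#' @return data.frame of class `model_comparison`: one row per fitted
#'   model with `k`, `n`, `rss`, `aicc`, `delta_aicc`, `weight`, ranked
#'   best first; coefficient estimates in the `coefficients` attribute.
#' @export
fit_diversity_models <- function(richness, midpoint_ma, boundary_ma = 66,
                                 log_transform = TRUE) {
  keep <- !(is.na(richness) | is.na(midpoint_ma))
  richness <- richness[keep]; midpoint_ma <- midpoint_ma[keep]
  y <- if (log_transform) {
    stopifnot(all(richness > 0))
    log(richness)
  } else richness
  # time increases toward the present so positive slopes mean increase
  time <- -midpoint_ma
  phase <- factor(ifelse(midpoint_ma < boundary_ma, "post", "pre"),
                  levels = c("pre", "post"))
  dat <- data.frame(y = y, time = time, phase = phase)
  forms <- list(intercept_only = y ~ 1,
                time = y ~ time,
                time_plus_phase = y ~ time + phase,
                time_by_phase = y ~ time * phase,
                phase_only = y ~ phase)
  n <- nrow(dat)
  one_phase <- length(unique(dat$phase)) < 2L
  rows <- list(); coefs <- list()
  for (nm in names(forms)) {
    if (one_phase && grepl("phase", nm)) {
      # all data points fall in a single diversification phase: phase
      # terms are inestimable
      rows[[nm]] <- data.frame(model = nm, k = NA_integer_, n = n,
                               rss = NA_real_, aicc = NA_real_,
                               skipped = TRUE)
      next
    }
    fit <- stats::lm(forms[[nm]], data = dat)
    k <- length(stats::coef(fit)) + 1L # + residual variance
    if (n - k - 1L <= 0L) {
      rows[[nm]] <- data.frame(model = nm, k = k, n = n, rss = NA_real_,
                               aicc = NA_real_, skipped = TRUE)
      next
    }
    rss <- sum(stats::residuals(fit)^2)
    aicc <- n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    rows[[nm]] <- data.frame(model = nm, k = k, n = n, rss = rss,
                             aicc = aicc, skipped = FALSE)
    coefs[[nm]] <- stats::coef(fit)
  }
  tab <- do.call(rbind, rows)
  ok <- !tab$skipped
  tab$delta_aicc <- NA_real_
  tab$weight <- NA_real_
  if (any(ok)) {
    tab$delta_aicc[ok] <- tab$aicc[ok] - min(tab$aicc[ok])
    w <- exp(-tab$delta_aicc[ok] / 2)
    tab$weight[ok] <- w / sum(w)
  }
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  attr(tab, "coefficients") <- coefs
  attr(tab, "boundary_ma") <- boundary_ma
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("diversification model comparison (AICc)\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Linear model with AR(1) errors
#'
#' Maximum-likelihood GLS fit of `y` on the predictor columns with
#' first-order autoregressive residuals over the (ordered) series — the
#' standard correction for temporal autocorrelation in bin-level time
#' series. With `phi` fixed at 0 the fit reduces to OLS.
#'
#' @param y Response, ordered old to young.
#' @param predictors data.frame (or vector) of predictors in the same
#'   order.
#' @param phi Optional fixed AR(1) coefficient; default NULL estimates it
#'   by ML.
#' @return List: `coefficients`, `phi`, `logLik`, `aicc`, `converged`.
#' @export
gls_ar1_fit <- function(y, predictors, phi = NULL) {
  dat <- as.data.frame(predictors)
  if (is.null(names(predictors)) && ncol(dat) == 1L) names(dat) <- "x"
  dat$y <- y
  dat$.ord <- seq_len(nrow(dat))
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  if (nrow(dat) < 8L) stop("need at least 8 complete observations")
  rhs <- paste(setdiff(names(dat), c("y", ".ord")), collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))
  corr <- if (is.null(phi)) nlme::corAR1(form = ~ .ord)
  else nlme::corAR1(value = phi, form = ~ .ord, fixed = TRUE)
  fit <- tryCatch(
    nlme::gls(form, data = dat, correlation = corr, method = "ML"),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(coefficients = NULL, phi = NA_real_, logLik = NA_real_,
                aicc = NA_real_, converged = FALSE))
  phi_hat <- if (is.null(phi)) {
    unname(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  } else phi
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- nrow(dat)
  aicc <- -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  list(coefficients = stats::coef(fit), phi = phi_hat,
       logLik = as.numeric(ll), aicc = aicc, converged = TRUE,
       se = sqrt(diag(stats::vcov(fit))))
}

#' Slope of diversity on time within an interval
#'
#' OLS regression of log richness on age over data points restricted to
#' `[late_ma, early_ma]`, with a two-sided t-test on the slope — used to
#' ask whether standing regional diversity trends within an era.
#'
#' @param richness Richness values (cluster medians).
#' @param midpoint_ma Ages (Ma).
#' @param early_ma,late_ma Interval bounds (older, younger).
#' @param log_transform Log the response (default TRUE).
#' @return List: `slope` (per Myr toward the present), `p_value`,
#'   `n_points`.
#' @export
interval_slope_test <- function(richness, midpoint_ma, early_ma, late_ma = 0,
                                log_transform = TRUE) {
  stopifnot(early_ma > late_ma)
  keep <- !is.na(richness) & !is.na(midpoint_ma) &
    midpoint_ma <= early_ma & midpoint_ma >= late_ma
  richness <- richness[keep]; midpoint_ma <- midpoint_ma[keep]
  if (length(richness) < 5L)
    stop("fewer than 5 data points in the interval")
  y <- if (log_transform) log(richness) else richness
  fit <- stats::lm(y ~ I(-midpoint_ma))
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       p_value = sm$coefficients[2L, 4L],
       r_squared = sm$r.squared,
       n_points = length(y))
}
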