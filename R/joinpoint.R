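#' Assemble a trend-analysis input series
#'
#' Annual rates with standard errors, ready for segmented log-linear
#' fitting. The model works on `log(rate)` with weights
#' `1 / SE(log rate)^2` where `SE(log rate) = SE(rate) / rate` (delta
#' method). Years with a zero rate cannot be logged; they are offset by
#' half the smallest positive rate in the series and flagged.
#'
#' @param years Ordered integer years (1-year spacing).
#' @param rates Annual rates (>= 0; zeros are offset and flagged).
#' @param se Standard errors of the rates (> 0). For Rubin-pooled series
#'   pass the square root of the total variance.
#' @return An object of class `trend_input`.
#' @export
trend_input <- function(years, rates, se) {
  n <- length(years)
  if (length(rates) != n || length(se) != n) {
    stop("years, rates and se must have equal length")
  }
  if (n >= 2 && any(diff(years) != 1)) stop("years must be consecutive")
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (any(se <= 0)) stop("standard errors must be positive")
  zero <- rates == 0
  if (all(zero)) stop("all rates are zero; nothing to fit")
  adj <- rates
  if (any(zero)) adj[zero] <- min(rates[rates > 0]) / 2
  structure(list(
    years = as.integer(years), rates = rates, se = se,
    log_rate = log(adj), weights = (adj / se)^2,
    zero_adjusted = zero
  ), class = "trend_input")
}

# admissible joinpoint position vectors (indices into the year grid):
# >= 3 observations strictly between a joinpoint and either end, and >= 3
# strictly between consecutive joinpoints
admissible_taus <- function(n, k, min_tail = 3L, min_gap = 3L) {
  if (k == 0) return(list(integer(0)))
  lo <- min_tail + 1L
  hi <- n - min_tail
  if (hi < lo) return(list())
  combos <- list()
  rec <- function(prefix, start) {
    depth <- length(prefix)
    if (depth == k) {
      combos[[length(combos) + 1L]] <<- prefix
      return()
    }
    for (j in start:hi) {
      if (hi - j < (k - depth - 1L) * (min_gap + 1L)) break
      rec(c(prefix, j), j + min_gap + 1L)
    }
  }
  rec(integer(0), lo)
  combos
}

segment_basis <- function(x, tau_x) {
  b <- cbind(1, x)
  for (t in tau_x) b <- cbind(b, pmax(x - t, 0))
  b
}

wls_fit <- function(X, y, w) {
  sw <- sqrt(w)
  f <- lm.fit(X * sw, y * sw)
  sse <- sum(f$residuals^2)
  p <- ncol(X)
  XtX_inv <- chol2inv(chol(crossprod(X * sw)))
  list(coef = f$coefficients, sse = sse, df = length(y) - p,
       cov_unscaled = XtX_inv, fitted = drop(X %*% f$coefficients))
}

#' Fit a segmented log-linear trend with k joinpoints
#'
#' Weighted least squares of `log(rate)` on the continuous
#' piecewise-linear basis, with an exhaustive grid search (1-year grid)
#' over all admissible joinpoint locations — at least three observations
#' between a joinpoint and either end of the series and between
#' consecutive joinpoints. The SSE-minimizing location vector wins; ties
#' break to the earliest vector in lexicographic order (the enumeration
#' order).
#'
#' @param input A [trend_input()].
#' @param k Number of joinpoints (>= 0).
#' @return An object of class `joinpoint_model` with joinpoint years
#'   (`tau`), segment slopes and covariance, SSE, residual df, fitted
#'   values and the grid-search trace.
#' @export
fit_segmented <- function(input, k) {
  stopifnot(inherits(input, "trend_input"))
  n <- length(input$years)
  combos <- admissible_taus(n, k)
  if (!length(combos)) {
    stop("cannot place ", k, " joinpoint(s) in ", n, " observations: ",
         "need 3 observations from each joinpoint to either end and 3 ",
         "between consecutive joinpoints")
  }
  x <- as.numeric(input$years)
  y <- input$log_rate
  w <- input$weights
  best <- NULL
  sse_trace <- numeric(length(combos))
  for (i in seq_along(combos)) {
    X <- segment_basis(x, x[combos[[i]]])
    f <- wls_fit(X, y, w)
    sse_trace[i] <- f$sse
    if (is.null(best) || f$sse < best$sse - 1e-12) {
      best <- f
      best$taus <- combos[[i]]
    }
  }
  p <- 2L + k
  sigma2 <- if (best$df > 0) best$sse / best$df else 0
  V <- sigma2 * best$cov_unscaled
  # slope of segment i: beta_1 + sum of the first (i-1) slope changes
  L <- matrix(0, k + 1L, p)
  L[, 2] <- 1
  if (k > 0) for (i in seq_len(k)) L[(i + 1):(k + 1), 2 + i] <- 1
  slopes <- drop(L %*% best$coef)
  slope_cov <- L %*% V %*% t(L)
  structure(list(
    k = k, tau = input$years[best$taus], tau_index = best$taus,
    coef = best$coef, vcov = V, slopes = slopes, slope_cov = slope_cov,
    sse = best$sse, df = best$df, fitted = best$fitted,
    input = input, sse_trace = sse_trace, combos = combos
  ), class = "joinpoint_model")
}

#' Per-segment annual percent change
#'
#' `APC_i = 100 (exp(b_i) - 1)` for the slope of each segment, with a
#' t-interval on the residual degrees of freedom.
#'
#' @param model A fitted [fit_segmented()] / [permutation_select()] model.
#' @param alpha Two-sided error level.
#' @return A tibble with one row per segment: start/end years, slope,
#'   APC and its confidence bounds, and the two-sided p-value for zero
#'   slope.
#' @export
apc <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "joinpoint_model"))
  yrs <- model$input$years
  bounds <- c(yrs[1], model$tau, yrs[length(yrs)])
  se <- sqrt(pmax(diag(model$slope_cov), 0))
  tq <- qt(1 - alpha / 2, df = max(model$df, 1))
  b <- model$slopes
  tibble::tibble(
    segment = seq_along(b),
    start = bounds[-length(bounds)], end = bounds[-1],
    slope = b, slope_se = se,
    apc = 100 * (exp(b) - 1),
    ci_low = 100 * (exp(b - tq * se) - 1),
    ci_high = 100 * (exp(b + tq * se) - 1),
    p_value = 2 * stats::pt(-abs(ifelse(se > 0, b / se, Inf)),
                            df = max(model$df, 1))
  )
}

#' Average annual percent change over a period
#'
#' The segment-length-weighted average slope, back-transformed:
#' `AAPC = 100 (exp(sum(L_i b_i) / sum(L_i)) - 1)` with `L_i` the years of
#' segment i inside the period. The variance of the weighted slope comes
#' from the WLS covariance of the segment slopes (fixed joinpoint
#' locations); the interval uses normal quantiles.
#'
#' @param model A fitted `joinpoint_model`.
#' @param period Length-2 year range, defaulting to the full series.
#' @param alpha Two-sided error level.
#' @return A one-row tibble with aapc, ci_low, ci_high, and the weighted
#'   slope and its SE.
#' @export
aapc <- function(model, period = NULL, alpha = 0.05) {
  stopifnot(inherits(model, "joinpoint_model"))
  yrs <- model$input$years
  period <- period %||% range(yrs)
  if (period[1] < yrs[1] || period[2] > yrs[length(yrs)] ||
      period[1] >= period[2]) {
    stop("period must lie within the fitted year range")
  }
  bounds <- c(yrs[1], model$tau, yrs[length(yrs)])
  L <- pmax(pmin(bounds[-1], period[2]) - pmax(bounds[-length(bounds)],
                                               period[1]), 0)
  wsum <- sum(L)
  cvec <- L / wsum
  est <- sum(cvec * model$slopes)
  se <- sqrt(drop(t(cvec) %*% model$slope_cov %*% cvec))
  z <- qnorm(1 - alpha / 2)
  tibble::tibble(
    start = period[1], end = period[2],
    slope = est, slope_se = se,
    aapc = 100 * (exp(est) - 1),
    ci_low = 100 * (exp(est - z * se) - 1),
    ci_high = 100 * (exp(est + z * se) - 1)
  )
}

# precompute, for every admissible tau combo of a given k, the orthonormal
# column basis of the weighted design; SSE for any (weighted) response is
# then ||y||^2 - ||Q'y||^2, which vectorizes over thousands of permuted
# responses at once
grid_projectors <- function(x, w, k) {
  combos <- admissible_taus(length(x), k)
  if (!length(combos)) stop("no admissible joinpoint placements for k = ", k)
  sw <- sqrt(w)
  Qs <- lapply(combos, function(cb) {
    qr.Q(qr(segment_basis(x, x[cb]) * sw))
  })
  list(combos = combos, Q = do.call(cbind, Qs),
       sizes = vapply(Qs, ncol, integer(1)))
}

min_sse_over_grid <- function(proj, Ytil) {
  # Ytil: n x B matrix of weighted responses
  z2 <- crossprod(proj$Q, Ytil)^2           # total_cols x B
  tot <- colSums(Ytil^2)
  grp <- rep(seq_along(proj$sizes), proj$sizes)
  expl <- rowsum(z2, grp)                   # combos x B
  sse <- sweep(-expl, 2, tot, "+")
  list(min = apply(sse, 2, min), argmin = apply(sse, 2, which.min))
}

#' Select the number of joinpoints by Monte Carlo permutation tests
#'
#' Sequential testing: starting at `k_min`, each null `k = k0` is tested
#' against the alternative `k = k_max` at Bonferroni-split level
#' `alpha / (k_max - k0)`. The test statistic is the F-ratio of the
#' weighted SSEs of the best-fitting null and alternative models; its
#' permutation distribution is obtained by shuffling the standardized
#' (weight-scaled) residuals of the null fit, rebuilding the response,
#' and re-running both grid searches on every permuted series. The
#' permutation p-value is `(1 + #{F* >= F}) / (1 + n_perm)`. The first
#' non-rejected null is selected; if every null is rejected the model
#' keeps `k_max` joinpoints.
#'
#' @param input A [trend_input()].
#' @param k_min,k_max Joinpoint search range.
#' @param n_perm Permutations per test (default 4500).
#' @param alpha Overall significance level of the sequence.
#' @param seed Integer seed (required: permutation selection is Monte
#'   Carlo and must be reproducible).
#' @return The selected `joinpoint_model`, with the per-test permutation
#'   p-values and significance cutoffs in `$selection`.
#' @export
permutation_select <- function(input, k_min = 0L, k_max = 3L,
                               n_perm = 4500L, alpha = 0.05, seed) {
  stopifnot(inherits(input, "trend_input"))
  if (missing(seed)) stop("seed is required for reproducible selection")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  n <- length(input$years)
  x <- as.numeric(input$years)
  w <- input$weights
  # verify k_max is admissible before testing
  if (!length(admissible_taus(n, k_max))) {
    stop("k_max = ", k_max, " is not admissible for ", n, " observations")
  }
  set.seed(substream_seed(seed, "trends"))
  tests <- list()
  selected <- k_max
  for (k0 in k_min:(max(k_min, k_max - 1L))) {
    if (k0 >= k_max) break
    fit0 <- fit_segmented(input, k0)
    fit1 <- fit_segmented(input, k_max)
    df0 <- fit0$df
    df1 <- fit1$df
    f_obs <- ((fit0$sse - fit1$sse) / (df0 - df1)) /
      (fit1$sse / max(df1, 1))
    # permutation distribution under the k0 null
    sw <- sqrt(w)
    res_std <- (input$log_rate - fit0$fitted) * sw
    perm_idx <- replicate(n_perm, sample.int(n))
    Ytil <- fit0$fitted * sw + matrix(res_std[perm_idx], n, n_perm)
    proj0 <- grid_projectors(x, w, k0)
    proj1 <- grid_projectors(x, w, k_max)
    sse0 <- min_sse_over_grid(proj0, Ytil)$min
    sse1 <- min_sse_over_grid(proj1, Ytil)$min
    f_perm <- ((sse0 - sse1) / (df0 - df1)) / (sse1 / max(df1, 1))
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
    cutoff <- alpha / (k_max - k0)
    tests[[length(tests) + 1L]] <- tibble::tibble(
      k_null = k0, k_alt = k_max, f_obs = f_obs, p_value = p,
      cutoff = cutoff, rejected = p < cutoff
    )
    if (p >= cutoff) {
      selected <- k0
      break
    }
  }
  model <- fit_segmented(input, selected)
  model$selection <- dplyr::bind_rows(tests)
  model$n_perm <- n_perm
  model$alpha <- alpha
  model
}
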