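years23 <- 1993:2015

piecewise_rates <- function(apc1, apc2, change_year, base = 50,
                            noise_sd = 0, years = years23) {
  b1 <- log(1 + apc1 / 100)
  b2 <- log(1 + apc2 / 100)
  t <- years - years[1]
  tc <- change_year - years[1]
  r <- base * exp(b1 * pmin(t, tc) + b2 * pmax(t - tc, 0))
  if (noise_sd > 0) r <- r * exp(rnorm(length(r), 0, noise_sd))
  r
}

test_that("noise-free log-linear data are interpolated exactly", {
  r <- 50 * exp(log(1.03) * (years23 - 1993))
  ti <- trend_input(years23, r, se = 0.02 * r)
  m <- fit_segmented(ti, 0)
  expect_equal(m$slopes, log(1.03), tolerance = 1e-10)
  expect_lt(m$sse, 1e-18)
  a <- apc(m)
  expect_equal(a$apc, 3, tolerance = 1e-8)
})

test_that("APC transforms slopes exactly", {
  r <- 50 * exp(log(1.05) * (years23 - 1993))
  m <- fit_segmented(trend_input(years23, r, se = 0.02 * r), 0)
  expect_equal(apc(m)$apc, 5, tolerance = 1e-9)
  flat <- rep(50, 23)
  m0 <- fit_segmented(trend_input(years23, flat, se = rep(1, 23)), 0)
  expect_equal(apc(m0)$apc, 0, tolerance = 1e-12)
})

test_that("the admissible grid and the fit match a brute-force oracle", {
  # 10 points, 1 joinpoint: exactly positions 4-7 are admissible
  taus <- registrytrends:::admissible_taus(10, 1)
  expect_equal(unlist(taus), 4:7)
  # spacing rule for two joinpoints
  taus2 <- registrytrends:::admissible_taus(11, 2)
  expect_true(all(vapply(taus2, function(t) t[2] - t[1] >= 4, logical(1))))

  yrs <- 2001:2010
  set.seed(42)
  r <- 30 * exp(0.02 * (yrs - 2001)) * exp(rnorm(10, 0, 0.05))
  se <- 0.03 * r
  ti <- trend_input(yrs, r, se)
  m <- fit_segmented(ti, 1)
  # independent oracle: plain weighted lm per admissible tau
  oracle <- sapply(4:7, function(j) {
    x <- as.numeric(yrs)
    xx <- pmax(x - x[j], 0)
    f <- lm(log(r) ~ x + xx, weights = (r / se)^2)
    sum((r / se)^2 * residuals(f)^2)
  })
  expect_equal(m$sse, min(oracle), tolerance = 1e-8)
  expect_equal(m$tau, yrs[(4:7)[which.min(oracle)]])
})

test_that("grid search recovers an injected slope change", {
  set.seed(7)
  r <- piecewise_rates(3, -3, 2009, noise_sd = 0.01)
  ti <- trend_input(years23, r, se = 0.02 * r)
  m <- fit_segmented(ti, 1)
  expect_equal(m$tau, 2009)
  expect_error(fit_segmented(trend_input(2001:2006, rep(10, 6),
                                         rep(0.5, 6)), 1),
               "3")
})

test_that("SSE is non-increasing in k and invariant taus under scaling", {
  set.seed(12)
  r <- piecewise_rates(2, -1, 2006, noise_sd = 0.03)
  ti <- trend_input(years23, r, se = 0.02 * r)
  sses <- vapply(0:3, function(k) fit_segmented(ti, k)$sse, numeric(1))
  expect_true(all(diff(sses) <= 1e-9))
  # multiplying all rates by a constant shifts the intercept only
  m1 <- fit_segmented(ti, 2)
  ti10 <- trend_input(years23, 10 * r, se = 10 * 0.02 * r)
  m2 <- fit_segmented(ti10, 2)
  expect_equal(m1$tau, m2$tau)
  expect_equal(m1$slopes, m2$slopes, tolerance = 1e-9)
  expect_equal(apc(m1)$apc, apc(m2)$apc, tolerance = 1e-8)
  expect_equal(aapc(m1)$aapc, aapc(m2)$aapc, tolerance = 1e-8)
})

test_that("AAPC is the length-weighted slope average with sane bounds", {
  set.seed(3)
  r <- piecewise_rates(4, -2, 2010, noise_sd = 0.02)
  ti <- trend_input(years23, r, se = 0.02 * r)
  m <- fit_segmented(ti, 1)
  a <- aapc(m)
  L1 <- m$tau - 1993
  L2 <- 2015 - m$tau
  hand <- 100 * (exp((L1 * m$slopes[1] + L2 * m$slopes[2]) / (L1 + L2)) - 1)
  expect_equal(a$aapc, hand, tolerance = 1e-10)
  segs <- apc(m)
  expect_gte(a$aapc, min(segs$apc) - 1e-9)
  expect_lte(a$aapc, max(segs$apc) + 1e-9)
  expect_error(aapc(m, period = c(1980, 2015)), "within")
})

test_that("single-segment AAPC equals its APC to machine precision", {
  set.seed(5)
  for (i in 1:10) {
    r <- 40 * exp(rnorm(1, 0, 0.03) * (years23 - 1993)) *
      exp(rnorm(23, 0, 0.03))
    m <- fit_segmented(trend_input(years23, r, se = 0.02 * r), 0)
    expect_equal(aapc(m)$aapc, apc(m)$apc, tolerance = 1e-12)
  }
})

test_that("zero rates are offset, flagged and fittable", {
  r <- c(0, 2, 3, 2, 4, 3, 2, 3)
  ti <- trend_input(2001:2008, r, se = rep(0.5, 8))
  expect_true(ti$zero_adjusted[1])
  expect_equal(exp(ti$log_rate[1]), 1)   # half the smallest positive rate
  expect_s3_class(fit_segmented(ti, 0), "joinpoint_model")
  expect_error(trend_input(2001:2003, c(0, 0, 0), rep(1, 3)), "all rates")
})

test_that("permutation selection is deterministic and controlled", {
  set.seed(81)
  r <- piecewise_rates(3, -3, 2009, noise_sd = 0.015)
  ti <- trend_input(years23, r, se = 0.02 * r)
  s1 <- permutation_select(ti, k_max = 2, n_perm = 299, seed = 9)
  s2 <- permutation_select(ti, k_max = 2, n_perm = 299, seed = 9)
  expect_identical(s1$selection, s2$selection)
  expect_identical(s1$tau, s2$tau)
  expect_gte(s1$k, 1)
  expect_error(permutation_select(ti, k_max = 2, n_perm = 299),
               "seed")
  expect_warning(permutation_select(ti, k_max = 1, n_perm = 50, seed = 1),
                 "coarse")
})
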