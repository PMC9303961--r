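toy_standard <- function(weights) {
  tibble::tibble(age_band = paste0("b", seq_along(weights)),
                 weight = weights / sum(weights))
}

test_that("direct standardization matches hand arithmetic", {
  s1 <- toy_standard(1)
  e1 <- asir(c(b1 = 10), c(b1 = 100000), s1)
  expect_equal(e1$rate, 10)
  expect_equal(e1$variance, 10)
  expect_equal(e1$case_count, 10)

  # equal crude rates across bands: standardized equals the crude rate
  s <- toy_standard(c(0.2, 0.3, 0.5))
  e <- asir(c(b1 = 5, b2 = 10, b3 = 20),
            c(b1 = 50000, b2 = 100000, b3 = 200000), s)
  expect_equal(e$rate, 10, tolerance = 1e-12)

  # two-band brute-force oracle (independent recomputation)
  s2 <- toy_standard(c(0.4, 0.6))
  d <- c(b1 = 5, b2 = 20)
  n <- c(b1 = 50000, b2 = 200000)
  e2 <- asir(d, n, s2)
  oracle_rate <- 1e5 * (0.4 * 5 / 50000 + 0.6 * 20 / 200000)
  oracle_var <- 1e10 * (0.4^2 * 5 / 50000^2 + 0.6^2 * 20 / 200000^2)
  expect_equal(e2$rate, oracle_rate, tolerance = 1e-10)
  expect_equal(e2$variance, oracle_var, tolerance = 1e-10)
  expect_equal(oracle_rate, 10)
  expect_equal(oracle_var, 5)

  expect_error(asir(c(b1 = -1), c(b1 = 1000), s1), "negative")
  expect_error(asir(c(b1 = 1), c(b1 = 0), s1), "positive")
  expect_error(asir(c(x = 1), c(x = 1000), toy_standard(c(1, 1))),
               "missing age bands")
})

test_that("standardization bounds and scale equivariance hold", {
  set.seed(11)
  for (i in 1:20) {
    nb <- sample(2:6, 1)
    s <- toy_standard(runif(nb, 0.1, 1))
    d <- setNames(rpois(nb, 20), s$age_band)
    n <- setNames(runif(nb, 1e4, 1e5), s$age_band)
    e <- asir(d, n, s)
    crude <- 1e5 * d / n
    expect_gte(e$rate, min(crude) - 1e-9)
    expect_lte(e$rate, max(crude) + 1e-9)
    e_half <- asir(d, 2 * n, s)
    expect_equal(e_half$rate, e$rate / 2, tolerance = 1e-12)
    e_scaled <- asir(3 * d, 3 * n, s)
    expect_equal(e_scaled$rate, e$rate, tolerance = 1e-12)
    expect_equal(e_scaled$variance, e$variance / 3, tolerance = 1e-12)
  }
})

test_that("gamma interval reduces to the Poisson closed form on one band", {
  s1 <- toy_standard(1)
  e <- asir(c(b1 = 10), c(b1 = 100000), s1)
  ci <- gamma_ci(e, method = "fay-feuer")
  # d cases at scale 1e5/n = 1: classic gamma interval for a Poisson count
  expect_equal(ci[["ci_low"]], qgamma(0.025, shape = 10, scale = 1),
               tolerance = 1e-10)
  expect_equal(ci[["ci_high"]], qgamma(0.975, shape = 11, scale = 1),
               tolerance = 1e-10)
  # tiwari and fay-feuer agree on a single band (mean = max)
  expect_equal(gamma_ci(e, method = "tiwari"), ci, tolerance = 1e-12)

  zero <- asir(c(b1 = 0), c(b1 = 100000), s1)
  ci0 <- gamma_ci(zero)
  expect_equal(ci0[["ci_low"]], 0)
  expect_gt(ci0[["ci_high"]], 0)
  expect_error(gamma_ci(e, alpha = 1.5), "alpha")
})

test_that("pooled series equal single-table series for identical stacks", {
  g <- tiny_registry()
  rec <- g$recoded
  complete <- rec
  complete$histology_group[is.na(complete$histology_group)] <- "ADC"
  complete$stage[is.na(complete$stage)] <- "localized"
  std <- scenario_standard(tiny_scenario())
  stack_same <- list(complete, complete, complete)
  rs <- pooled_rate_series(stack_same, g$population, std, sex = "male",
                           histology = "ADC")
  single <- pooled_rate_series(list(complete), g$population, std,
                               sex = "male", histology = "ADC")
  expect_equal(rs$rate, single$rate, tolerance = 1e-12)
  expect_equal(rs$B, rep(0, nrow(rs)), tolerance = 1e-12)
  expect_true(all(rs$ci_low <= rs$rate + 1e-9 &
                    rs$rate <= rs$ci_high + 1e-9))
})

test_that("pooled points average per-imputation rates; imputed >= complete-case", {
  g <- tiny_registry()
  rec <- g$recoded
  spec <- imputation_spec(m = 3, n_cycles = 2, seed = 23)
  stack <- multiple_impute(rec, spec)
  std <- scenario_standard(tiny_scenario())
  rs <- pooled_rate_series(stack, g$population, std, sex = "female",
                           histology = "ADC")
  imp <- rs[rs$source == "imputed", ]
  cc <- rs[rs$source == "complete_case", ]
  # pooled point is the arithmetic mean of per-imputation ASIRs
  for (y in c(1995L, 2005L, 2015L)) {
    per <- vapply(stack$imputations, function(im) {
      asir(
        setNames(as.vector(table(factor(
          im$age_band[im$sex == "female" & im$diag_year == y &
                        im$histology_group == "ADC"],
          levels = std$age_band))), std$age_band),
        setNames(
          tapply(g$population$person_years[g$population$sex == "female" &
                                             g$population$year == y],
                 factor(g$population$age_band[g$population$sex == "female" &
                                                g$population$year == y],
                        levels = std$age_band), sum),
          std$age_band),
        std)$rate
    }, numeric(1))
    expect_equal(imp$rate[imp$year == y], mean(per), tolerance = 1e-10)
  }
  # imputation only adds cases to a stratum
  expect_true(all(imp$rate >= cc$rate - 1e-9))
  # pooling consistency: total variance at least the within component
  expect_true(all(imp$variance >= imp$W - 1e-12))
})

test_that("identical series give unit IRR with covering intervals", {
  g <- tiny_registry()
  rec <- g$recoded
  complete <- rec
  complete$histology_group[is.na(complete$histology_group)] <- "ADC"
  complete$stage[is.na(complete$stage)] <- "localized"
  std <- scenario_standard(tiny_scenario())
  rs <- pooled_rate_series(list(complete, complete), g$population, std,
                           sex = "male")
  irr <- irr_series(rs, rs)
  expect_true(all(irr$defined))
  expect_equal(irr$irr, rep(1, nrow(irr)), tolerance = 1e-12)
  expect_true(all(irr$ci_low <= 1 & 1 <= irr$ci_high))
  other <- rs[rs$year != max(rs$year) & rs$source == "imputed", ]
  expect_error(irr_series(rs, other), "years")
})

test_that("a half-rate female scenario yields IRRs around 0.5", {
  cfg <- tiny_scenario(seed = 31, person_years = 6000)
  cfg$base_rates$female <- 0.5 * cfg$base_rates$male
  cfg$histology_mix$female <- cfg$histology_mix$male
  cfg$trend_spec$apc1 <- 0
  cfg$trend_spec$apc2 <- NA
  cfg$trend_spec$change_year <- NA
  g <- generate_registry(cfg)
  rec <- recode_stage(recode_histology(g$records))
  stack <- multiple_impute(rec, imputation_spec(m = 2, n_cycles = 1,
                                                seed = 32))
  std <- scenario_standard(cfg)
  f <- pooled_rate_series(stack, g$population, std, sex = "female")
  m <- pooled_rate_series(stack, g$population, std, sex = "male")
  irr <- irr_series(f, m)
  covered <- irr$ci_low <= 0.5 & 0.5 <= irr$ci_high
  expect_gte(mean(covered), 0.7)
  expect_lt(abs(mean(irr$irr) - 0.5), 0.05)
})
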