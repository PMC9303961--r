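test_that("population grid covers every stratum with the configured value", {
  cfg <- default_scenario(person_years = 100000)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 3 * 23 * 2 * 18)
  expect_true(all(pop$person_years == 100000))
  expect_identical(pop, generate_population(cfg))
})

test_that("invalid grids and trend change-points are rejected", {
  cfg <- default_scenario()
  bad <- cfg
  bad$years <- integer(0)
  expect_error(generate_population(bad), "empty")
  expect_error(inject_joinpoint_trend(cfg, "male", "ADC", apc1 = 1,
                                      apc2 = 2, change_year = 1993),
               "strictly inside")
  expect_error(inject_joinpoint_trend(cfg, "male", "ADC", apc1 = 1,
                                      apc2 = 2, change_year = 2015),
               "strictly inside")
  huge <- default_scenario()
  huge$base_rates$male[] <- 2e5
  expect_error(generate_registry(huge), "person-years")
})

test_that("injected trends shape expected rates as specified", {
  cfg <- default_scenario()
  flat <- inject_joinpoint_trend(cfg, "male", "SQC", apc1 = 0)
  expect_equal(registrytrends:::trend_factor(flat, "male", "SQC", "localized"),
               rep(1, 23))
  g3 <- inject_joinpoint_trend(cfg, "male", "SQC", apc1 = 3)
  tf <- registrytrends:::trend_factor(g3, "male", "SQC", "regional")
  expect_equal(tf[-1] / tf[-23], rep(1.03, 22), tolerance = 1e-12)
  two <- inject_joinpoint_trend(cfg, "male", "ADC", apc1 = 2.2,
                                apc2 = -0.5, change_year = 2010)
  tf2 <- registrytrends:::trend_factor(two, "male", "ADC", "distant")
  ratios <- tf2[-1] / tf2[-23]
  expect_equal(ratios[1:17], rep(1.022, 17), tolerance = 1e-12)
  expect_equal(ratios[18:22], rep(0.995, 5), tolerance = 1e-12)
})

test_that("degenerate masking model produces a fully observed registry", {
  g <- generate_registry(no_missing_scenario())
  expect_false(any(g$records$morphology_code %in% c(8010, 8046)))
  expect_false(any(g$records$stage_raw %in% c("", "Unknown")))
})

test_that("registry generation is seed-deterministic and conserving", {
  cfg <- tiny_scenario(seed = 77)
  g1 <- generate_registry(cfg)
  g2 <- generate_registry(cfg)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truth, g2$truth)
  expect_equal(nrow(g1$records), nrow(g1$truth))
  expect_identical(g1$records$case_id, g1$truth$case_id)
  # masking only touches histology/stage: unmasked rows agree with truth
  rec <- recode_stage(recode_histology(g1$records))
  obs_h <- !g1$truth$hist_masked
  expect_identical(rec$histology_group[obs_h], g1$truth$histology[obs_h])
  obs_s <- !g1$truth$stage_masked
  expect_identical(rec$stage[obs_s], g1$truth$stage[obs_s])
})

test_that("nonspecific codes carry the correct candidate sets", {
  g <- tiny_registry()
  rec <- g$recoded
  r8046 <- rec$restriction[rec$morphology_code == 8046]
  expect_true(all(r8046 == "SQC|ADC|LAC|other_nsclc"))
  r8010 <- rec$restriction[rec$morphology_code == 8010]
  expect_true(all(r8010 == "SMC|SQC|ADC|LAC|other_nsclc"))
  # a masked record's truth always lies in its candidate set
  truth <- g$truth$histology[match(rec$case_id, g$truth$case_id)]
  masked <- rec$morphology_code %in% c(8010, 8046)
  ok <- mapply(function(tr, cand) tr %in% strsplit(cand, "|",
                                                   fixed = TRUE)[[1]],
               truth[masked], rec$restriction[masked])
  expect_true(all(ok))
})

test_that("masking follows the logistic MAR specification", {
  # +2 log-odds for age 80+ must show up empirically
  cfg <- tiny_scenario(seed = 13, person_years = 4500)
  cfg$miss_stage$age80 <- 2
  g <- generate_registry(cfg)
  expect_gt(nrow(g$records), 10000)
  miss <- g$records$stage_raw %in% c("", "Unknown")
  old <- g$records$age_years >= 80
  expect_gt(mean(miss[old]), mean(miss[!old]))

  # MAR within the maskable groups: regressing the indicator on the true
  # value plus the model's covariates leaves the truth uninformative
  g2 <- medium_registry()
  truth <- g2$truth
  rec <- g2$records
  eligible <- truth$histology != "other_unspec"
  d <- data.frame(
    miss = truth$hist_masked[eligible],
    truth_smc = truth$histology[eligible] == "SMC",
    sex = rec$sex[eligible], age80 = rec$age_years[eligible] >= 80,
    pref = rec$prefecture[eligible], obs = rec$obs_years[eligible],
    dco = rec$dco_flag[eligible],
    trt = with(rec[eligible, ], surgery | radiotherapy | chemotherapy |
                 laparoscopy)
  )
  fit <- glm(miss ~ truth_smc + sex + age80 + pref + obs + dco + trt,
             family = binomial, data = d)
  z <- coef(summary(fit))["truth_smcTRUE", "z value"]
  expect_lt(abs(z), 4)
})

test_that("default calibration hits the stated missingness targets", {
  g <- tiny_registry()   # same generating law, smaller n, loose check
  frac_h <- mean(g$records$morphology_code %in% c(8010, 8046))
  frac_s <- mean(g$records$stage_raw %in% c("", "Unknown"))
  expect_gt(frac_h, 0.08)
  expect_lt(frac_h, 0.14)
  expect_gt(frac_s, 0.20)
  expect_lt(frac_s, 0.28)
})
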