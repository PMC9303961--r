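test_that("restricted draws respect candidate sets exactly", {
  p <- c(SMC = 0.2, SQC = 0.2, ADC = 0.2, LAC = 0.2,
         other_nsclc = 0.1, other_unspec = 0.1)
  # singleton candidate set: that category with probability 1
  set.seed(1)
  draws <- replicate(50, restricted_draw(p, "SMC"))
  expect_true(all(draws == "SMC"))

  # 8046-style restriction: SMC never drawn
  set.seed(2)
  pm <- matrix(p, 10000, 6, byrow = TRUE, dimnames = list(NULL, names(p)))
  d <- restricted_draw(pm, "SQC|ADC|LAC|other_nsclc")
  expect_false(any(d %in% c("SMC", "other_unspec")))

  # renormalization arithmetic: uniform over a 4-set is 0.25 each
  set.seed(3)
  u <- matrix(1 / 6, 10000, 6, dimnames = list(NULL, names(p)))
  d2 <- restricted_draw(u, "SQC|ADC|LAC|other_nsclc")
  freq <- table(d2) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))

  # all-candidate-probability-zero falls back to uniform and reports it
  pz <- c(SMC = 1, SQC = 0, ADC = 0, LAC = 0,
          other_nsclc = 0, other_unspec = 0)
  set.seed(4)
  dz <- restricted_draw(pz, "SQC|ADC")
  expect_true(dz %in% c("SQC", "ADC"))
  expect_equal(attr(dz, "fallbacks"), 1L)
  expect_error(restricted_draw(p, "not_a_group"), "outside")
})

test_that("conditional models recover structure and degenerate cases", {
  g <- tiny_registry()
  rec <- g$recoded
  spec <- imputation_spec(m = 2, n_cycles = 1, seed = 3)

  # intercept-only model predicts observed category frequencies exactly
  spec0 <- imputation_spec(m = 2, n_cycles = 1, covariates = "1", seed = 3)
  fit0 <- fit_conditional(rec[!is.na(rec$stage), ], "stage", spec0)
  pr <- predict(fit0, newdata = rec[1:5, ], type = "probs")
  obs_freq <- as.vector(table(factor(rec$stage, levels = stage_levels()))) /
    sum(!is.na(rec$stage))
  expect_equal(as.vector(pr[1, ]), obs_freq, tolerance = 1e-6)

  # an empty category aborts with its name
  few <- rec[!is.na(rec$stage) & rec$stage != "distant", ]
  expect_error(fit_conditional(few, "stage", spec0), "distant")
})

test_that("imputation completes, restricts, and is reproducible", {
  g <- tiny_registry()
  rec <- g$recoded
  spec <- imputation_spec(m = 3, n_cycles = 2, seed = 17)
  stack <- multiple_impute(rec, spec)
  expect_equal(stack$m, 3)
  for (im in stack$imputations) {
    expect_false(anyNA(im$histology_group))
    expect_false(anyNA(im$stage))
    # hard restriction invariant on every record of every imputation
    m8046 <- rec$morphology_code == 8046
    expect_false(any(im$histology_group[m8046] %in%
                       c("SMC", "other_unspec")))
    m8010 <- rec$morphology_code == 8010
    expect_false(any(im$histology_group[m8010] == "other_unspec"))
    # untouched fields byte-identical
    keep <- setdiff(names(rec), c("histology_group", "stage"))
    expect_identical(im[keep], rec[keep])
    # observed values never altered
    obs <- !is.na(rec$histology_group)
    expect_identical(im$histology_group[obs], rec$histology_group[obs])
  }
  stack2 <- multiple_impute(rec, spec)
  expect_identical(stack$imputations, stack2$imputations)
})

test_that("an imputed stack round-trips through disk with provenance", {
  g <- tiny_registry()
  rec <- g$recoded[round(seq(1, nrow(g$recoded), length.out = 2000)), ]
  stack <- multiple_impute(rec, imputation_spec(m = 2, n_cycles = 1,
                                                cross_terms = FALSE,
                                                seed = 41))
  dir <- withr::local_tempdir()
  write_imputed_stack(stack, dir)
  expect_true(file.exists(file.path(dir, "imputation_01.csv")))
  back <- read_imputed_stack(dir)
  expect_equal(back$m, 2)
  expect_identical(back$miss_histology, stack$miss_histology)
  expect_identical(back$miss_stage, stack$miss_stage)
  expect_equal(back$imputations[[1]]$histology_group,
               stack$imputations[[1]]$histology_group)
  expect_equal(back$imputations[[2]]$stage, stack$imputations[[2]]$stage)
})

test_that("a complete input is returned unchanged with zero between-variance", {
  g <- generate_registry(no_missing_scenario())
  rec <- recode_stage(recode_histology(g$records))
  spec <- imputation_spec(m = 3, n_cycles = 1, seed = 2)
  one <- impute_once(rec, spec, 1)
  expect_identical(one$histology_group, rec$histology_group)
  expect_identical(one$stage, rec$stage)
  stack <- multiple_impute(rec, spec)
  shares <- vapply(stack$imputations,
                   function(im) mean(im$stage == "localized"), numeric(1))
  pooled <- rubin_pool(shares, rep(0.1, 3))
  expect_equal(pooled$B, 0)
  expect_true(pooled$degenerate)
  expect_equal(pooled$T, pooled$W)
})

test_that("Rubin pooling matches hand computation and its algebra", {
  p <- rubin_pool(c(5, 5, 5), c(0.04, 0.04, 0.04))
  expect_equal(p$point, 5)
  expect_equal(p$B, 0)
  expect_equal(p$T, 0.04)

  p2 <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p2$point, 2, tolerance = 1e-15)
  expect_equal(p2$W, 1, tolerance = 1e-15)
  expect_equal(p2$B, 1, tolerance = 1e-15)
  expect_equal(p2$T, 7 / 3, tolerance = 1e-15)
  expect_equal(p2$df, 2 * (1 + 1 / (4 / 3))^2, tolerance = 1e-12)

  expect_error(rubin_pool(1, 1), "at least two")
  expect_error(rubin_pool(c(1, 2), c(1, -1)), "nonnegative")

  # fuzz: T >= W and the decomposition identity always hold
  set.seed(8)
  for (i in 1:50) {
    m <- sample(2:25, 1)
    est <- rnorm(m, 10, 2)
    v <- rexp(m)
    pp <- rubin_pool(est, v)
    expect_gte(pp$T, pp$W)
    expect_equal(pp$T, pp$W + (1 + 1 / m) * pp$B, tolerance = 1e-12)
    expect_equal(pp$point, mean(est), tolerance = 1e-12)
  }
})
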