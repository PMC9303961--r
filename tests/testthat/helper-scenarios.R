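# shared scenario builders and a cross-file cache for expensive fixtures

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small registry for unit tests (~9k cases)
tiny_scenario <- function(seed = 5L, person_years = 3000) {
  default_scenario(seed = seed, person_years = person_years)
}

tiny_registry <- function() {
  cache_get("tiny_registry", function() {
    g <- generate_registry(tiny_scenario())
    g$recoded <- recode_stage(recode_histology(g$records))
    g
  })
}

# ~35k-case registry under the default generating law, for tests that
# need realistic power (missingness-association diagnostics, MAR checks)
medium_registry <- function() {
  cache_get("medium_registry", function() {
    g <- generate_registry(default_scenario(seed = 29L,
                                            person_years = 12000))
    g$recoded <- recode_stage(recode_histology(g$records))
    g
  })
}

# scenario with no masking at all
no_missing_scenario <- function(seed = 9L, person_years = 2000) {
  cfg <- default_scenario(seed = seed, person_years = person_years)
  cfg$miss_histology$intercept <- -30
  cfg$miss_stage$intercept <- -30
  cfg
}

# strictly survival-independent MAR masking: depends on sex and
# prefecture only, the two covariates unrelated to follow-up given the
# validation strata
survival_independent_scenario <- function(seed, person_years = 21500) {
  cfg <- default_scenario(seed = seed, person_years = person_years)
  for (mm in c("miss_histology", "miss_stage")) {
    cfg[[mm]]$age80 <- 0
    cfg[[mm]]$year <- 0
    cfg[[mm]]$no_treatment <- 0
    cfg[[mm]]$obs_years <- 0
    cfg[[mm]]$dco <- 0
  }
  cfg$miss_stage$intercept <- -1.5
  cfg
}

# deliberately MNAR: stage masking depends on the true stage being
# distant, which no MAR imputation model can see
mnar_scenario <- function(seed, person_years = 12000) {
  cfg <- survival_independent_scenario(seed, person_years)
  cfg$miss_stage$distant <- 2.0
  cfg$miss_stage$intercept <- -2.3
  cfg
}

# full-size default-scenario imputation run shared by the acceptance
# criteria (restriction invariant, marginal recovery, runtime budget)
default_big_run <- function() {
  cache_get("default_big_run", function() {
    cfg <- default_scenario(seed = 1234L)
    g <- generate_registry(cfg)
    rec <- recode_stage(recode_histology(g$records))
    t0 <- proc.time()
    stack <- multiple_impute(rec, imputation_spec(m = 20, n_cycles = 5,
                                                  seed = 4321L))
    elapsed <- (proc.time() - t0)[["elapsed"]]
    list(cfg = cfg, registry = g, records = rec, stack = stack,
         impute_seconds = elapsed)
  })
}

pooled_marginal <- function(stack, field, levels) {
  rowMeans(vapply(stack$imputations, function(im) {
    as.vector(table(factor(im[[field]], levels = levels))) / nrow(im)
  }, numeric(length(levels))))
}
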