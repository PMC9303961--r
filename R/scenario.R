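#' Build a synthetic-registry scenario configuration
#'
#' A scenario fully describes the data-generating process for a synthetic
#' population-based cancer registry: the prefecture x year x sex x age-band
#' grid, per-stratum person-years, baseline age- and sex-specific incidence,
#' the per-sex histology mix, time- and age-dependent stage composition
#' (including a stage-shift drift), per-series log-linear incidence trends,
#' two logistic missing-at-random masking models (nonspecific morphology
#' coding of histology; unknown/missing stage), exponential survival by
#' stage and histology, and the unknown-vs-missing and 8010-vs-8046 label
#' splits.
#'
#' All rates are cases per 100,000 person-years. Trend slopes are expressed
#' as annual percent changes (APC); internally a slope of `a` percent per
#' year multiplies expected counts by `(1 + a/100)` per calendar year.
#'
#' @param prefectures Character vector of registry areas.
#' @param years Inclusive integer range of diagnosis years.
#' @param person_years Person-years per prefecture x year x sex x age-band
#'   stratum (scalar, or vector of length `length(age_bands)` recycled over
#'   the rest of the grid).
#' @param base_rates Named list with one numeric vector per sex giving the
#'   baseline incidence per 100,000 person-years in each age band at the
#'   first year of the series.
#' @param histology_mix Named list with one probability vector per sex over
#'   the six histology groups (each sums to 1).
#' @param stage_spec List with per-histology baseline logits (localized and
#'   distant, relative to regional), per-year drifts `drift_loc` and
#'   `drift_dist` (the stage shift), and per-year-of-age effects `age_loc`
#'   and `age_dist` centred at age 70.
#' @param trend_spec Data frame with columns `sex`, `histology`, `stage`
#'   (NA = all stages), `apc1`, `apc2`, `change_year` describing piecewise
#'   log-linear incidence trends. See [inject_joinpoint_trend()].
#' @param miss_histology,miss_stage Coefficient lists for the two logistic
#'   MAR masking models (see [default_scenario()] for the fields).
#' @param survival_spec Matrix of exponential hazards (per year), rows =
#'   stages, columns = histology groups.
#' @param censor_year Administrative censoring year for follow-up.
#' @param p_8046 Probability that a masked non-SMC histology is coded 8046
#'   rather than 8010 (masked SMC is always 8010, since 8046 excludes SMC).
#' @param p_unknown_stage Probability that a masked stage is labelled
#'   "unknown" rather than left blank ("missing").
#' @param seed Integer seed recorded with the scenario.
#'
#' @return An object of class `scenario_config`.
#' @seealso [default_scenario()], [generate_registry()]
#' @export
scenario_config <- function(prefectures = c("Yamagata", "Fukui", "Nagasaki"),
                            years = 1993:2015,
                            person_years = 25000,
                            base_rates,
                            histology_mix,
                            stage_spec,
                            trend_spec,
                            miss_histology,
                            miss_stage,
                            survival_spec,
                            censor_year = 2017,
                            p_8046 = 0.12,
                            p_unknown_stage = 0.56,
                            seed = 1L) {
  age_bands <- c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
  cfg <- structure(list(
    prefectures = prefectures, years = as.integer(years),
    age_bands = age_bands,
    sex_levels = c("male", "female"),
    person_years = person_years,
    base_rates = base_rates, histology_mix = histology_mix,
    stage_spec = stage_spec, trend_spec = trend_spec,
    miss_histology = miss_histology, miss_stage = miss_stage,
    survival_spec = survival_spec, censor_year = censor_year,
    p_8046 = p_8046, p_unknown_stage = p_unknown_stage,
    seed = as.integer(seed)
  ), class = "scenario_config")
  validate_scenario(cfg)
  cfg
}

validate_scenario <- function(cfg) {
  if (length(cfg$years) < 1L || length(cfg$age_bands) < 1L) {
    stop("scenario grid is empty: need at least one year and one age band")
  }
  if (any(diff(cfg$years) != 1L)) stop("years must be a contiguous range")
  py <- cfg$person_years
  if (!length(py) %in% c(1L, length(cfg$age_bands)) || any(py <= 0)) {
    stop("person_years must be positive, scalar or one value per age band")
  }
  for (s in cfg$sex_levels) {
    mix <- cfg$histology_mix[[s]]
    if (length(mix) != length(HIST_LEVELS) || abs(sum(mix) - 1) > 1e-12 ||
        any(mix < 0)) {
      stop("histology_mix[['", s, "']] must be a probability vector over ",
           "the six histology groups summing to 1")
    }
    if (length(cfg$base_rates[[s]]) != length(cfg$age_bands) ||
        any(cfg$base_rates[[s]] < 0)) {
      stop("base_rates[['", s, "']] needs one nonnegative rate per age band")
    }
  }
  if (!all(dim(cfg$survival_spec) == c(length(STAGE_LEVELS),
                                       length(HIST_LEVELS))) ||
      any(cfg$survival_spec <= 0)) {
    stop("survival_spec must be a positive stage x histology hazard matrix")
  }
  if (cfg$p_8046 < 0 || cfg$p_8046 > 1 ||
      cfg$p_unknown_stage < 0 || cfg$p_unknown_stage > 1) {
    stop("label-split probabilities must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Default calibrated scenario
#'
#' The package's reference data-generating process: three prefectures,
#' diagnosis years 1993-2015, two sexes, eighteen 5-year age bands (0-4 to
#' 85+), a steep age gradient in baseline incidence with female rates about
#' 40% of male rates, a sex-dependent histology mix dominated by
#' adenocarcinoma among women, a stage composition drifting from regional
#' towards localized and distant disease over calendar time, per-histology
#' incidence trends (declining small-cell and squamous-cell disease among
#' men, rising adenocarcinoma in both sexes with a late-series slowdown),
#' and MAR masking models whose intercepts are calibrated so that overall
#' about 11% of cases carry a nonspecific morphology code and about 23.6%
#' an unknown/missing stage, with stage missingness declining steeply over
#' calendar time and both kinds of missingness elevated among women,
#' patients aged 80+, one prefecture, untreated patients and short
#' follow-up.
#'
#' At the default person-years the scenario yields roughly 60,000 cases
#' over the full grid.
#'
#' @param seed Integer seed stored in the configuration.
#' @param person_years Person-years per stratum; lower it to scale the
#'   registry down for quick runs.
#' @return A `scenario_config` object.
#' @export
default_scenario <- function(seed = 1L, person_years = 21500) {
  base_male <- c(0.5, 0.3, 0.3, 0.5, 1, 2, 3, 5,     # 0-39
                 10, 20, 40, 80, 150, 250, 380, 500, 600, 650)
  base_rates <- list(male = base_male, female = 0.4 * base_male)
  histology_mix <- list(
    male   = c(SMC = 0.116, SQC = 0.277, ADC = 0.389, LAC = 0.023,
               other_nsclc = 0.015, other_unspec = 0.180),
    female = c(SMC = 0.050, SQC = 0.074, ADC = 0.665, LAC = 0.011,
               other_nsclc = 0.011, other_unspec = 0.189)
  )
  stage_spec <- list(
    # baseline logits at the first year, age 70, relative to regional
    loc0  = c(SMC = -1.48, SQC = -0.46, ADC = -0.26, LAC = -0.78,
              other_nsclc = -0.78, other_unspec = -0.78),
    dist0 = c(SMC = 0.37, SQC = -0.62, ADC = 0.06, LAC = 0.39,
              other_nsclc = 0.39, other_unspec = 0.39),
    drift_loc = 0.045, drift_dist = 0.022,   # per calendar year: stage shift
    age_loc = -0.008, age_dist = 0.012       # per year of age, centred at 70
  )
  trend_spec <- tibble::tibble(
    sex = rep(c("male", "female"), each = 6),
    histology = rep(HIST_LEVELS, 2),
    stage = NA_character_,
    apc1 = c(-0.5, -0.8, 2.2, -2.0, 2.0, 0.0,
             0.2, 0.2, 3.3, -3.0, 2.0, 0.0),
    apc2 = c(NA, NA, -0.5, NA, NA, NA,
             NA, NA, -2.7, NA, NA, NA),
    change_year = c(NA, NA, 2010, NA, NA, NA,
                    NA, NA, 2012, NA, NA, NA)
  )
  # MAR masking models on the logit scale; intercepts calibrated to the
  # target overall fractions (~11% nonspecific histology, ~23.6% stage)
  miss_histology <- list(
    intercept = -2.48, female = 0.17, age80 = 0.35,
    prefecture = c(Yamagata = 0, Fukui = 0, Nagasaki = 0.4),
    year = 0, no_treatment = 0.5, obs_years = -0.05, dco = 0.8
  )
  # `distant` is a coefficient on the TRUE stage being distant: zero under
  # MAR (the default); set it nonzero to build a deliberately MNAR misuse
  # scenario for diagnostics-power tests
  miss_stage <- list(
    intercept = -1.31, female = 0.05, age80 = 0.6,
    prefecture = c(Yamagata = 0, Fukui = 0, Nagasaki = 0.4),
    year = -0.055, no_treatment = 0.6, obs_years = -0.04, dco = 1.0,
    distant = 0
  )
  survival_spec <- rbind(
    localized = c(0.30, 0.10, 0.06, 0.12, 0.10, 0.12),
    regional  = c(0.55, 0.28, 0.22, 0.30, 0.28, 0.30),
    distant   = c(1.10, 0.85, 0.75, 0.90, 0.85, 0.90)
  )
  colnames(survival_spec) <- HIST_LEVELS
  scenario_config(
    person_years = person_years, base_rates = base_rates,
    histology_mix = histology_mix, stage_spec = stage_spec,
    trend_spec = trend_spec, miss_histology = miss_histology,
    miss_stage = miss_stage, survival_spec = survival_spec, seed = seed
  )
}

#' Inject a piecewise log-linear trend into a scenario
#'
#' Overrides (or adds) the incidence trend for one series so that expected
#' rates follow `exp(b1 * t)` up to `change_year` and continue with slope
#' `b2 = log(1 + apc2/100)` afterwards, where `b1 = log(1 + apc1/100)` and
#' `t` counts calendar years from the start of the series. With
#' `apc2 = NULL` the series is a single log-linear segment. This is the
#' generator-side counterpart of the joinpoint model and is what trend
#' recovery tests run against.
#'
#' @param cfg A `scenario_config`.
#' @param sex,histology,stage Series key; `stage = NA` applies the trend to
#'   all stages of the histology group.
#' @param apc1,apc2 Annual percent changes before/after the change year.
#' @param change_year Calendar year of the slope change; must lie strictly
#'   inside the configured year range (omit for a single segment).
#' @return The modified `scenario_config`.
#' @export
inject_joinpoint_trend <- function(cfg, sex, histology, stage = NA,
                                   apc1, apc2 = NULL, change_year = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(change_year)) {
    rng <- range(cfg$years)
    if (change_year <= rng[1] || change_year >= rng[2]) {
      stop("change_year must lie strictly inside the year range ",
           rng[1], "-", rng[2])
    }
    if (is.null(apc2)) stop("change_year given without apc2")
  }
  ts <- cfg$trend_spec
  hit <- ts$sex == sex & ts$histology == histology &
    (is.na(stage) & is.na(ts$stage) |
       (!is.na(stage) & !is.na(ts$stage) & ts$stage == stage))
  row <- tibble::tibble(sex = sex, histology = histology,
                        stage = as.character(stage), apc1 = apc1,
                        apc2 = if (is.null(apc2)) NA_real_ else apc2,
                        change_year = if (is.null(change_year)) NA_real_
                                      else change_year)
  cfg$trend_spec <- dplyr::bind_rows(ts[!hit, ], row)
  cfg
}

# multiplicative trend factor per year for one (sex, histology, stage) cell
trend_factor <- function(cfg, sex, histology, stage) {
  t <- cfg$years - cfg$years[1]
  ts <- cfg$trend_spec
  hit <- ts$sex == sex & ts$histology == histology &
    (is.na(ts$stage) | ts$stage == stage)
  if (!any(hit)) return(rep(1, length(t)))
  # stage-specific rows take precedence over all-stage rows
  row <- ts[hit, ][order(is.na(ts$stage[hit])), ][1, ]
  b1 <- log1p(row$apc1 / 100)
  if (is.na(row$change_year)) return(exp(b1 * t))
  tc <- row$change_year - cfg$years[1]
  b2 <- log1p(row$apc2 / 100)
  exp(b1 * pmin(t, tc) + b2 * pmax(t - tc, 0))
}

# stage probabilities for one histology at given years and mid-band age
stage_probs <- function(cfg, histology, year, age_mid) {
  sp <- cfg$stage_spec
  t <- year - cfg$years[1]
  a <- age_mid - 70
  l_loc <- sp$loc0[[histology]] + sp$drift_loc * t + sp$age_loc * a
  l_dist <- sp$dist0[[histology]] + sp$drift_dist * t + sp$age_dist * a
  e <- cbind(localized = exp(l_loc), regional = 1, distant = exp(l_dist))
  e / rowSums(e)
}
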