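#' Person-year denominators for a scenario grid
#'
#' Expands the configured person-years over the full prefecture x year x
#' sex x age-band grid. With the default scalar specification every stratum
#' receives the same denominator; a vector of length `length(age_bands)`
#' gives an age-shaped population.
#'
#' @param cfg A `scenario_config`.
#' @return A tibble with columns `prefecture`, `year`, `sex`, `age_band`,
#'   `person_years`, one row per stratum.
#' @export
generate_population <- function(cfg) {
  validate_scenario(cfg)
  grid <- tidyr::expand_grid(
    prefecture = cfg$prefectures, year = cfg$years,
    sex = cfg$sex_levels, age_band = cfg$age_bands
  )
  py <- rep_len(cfg$person_years, length(cfg$age_bands))
  grid$person_years <- py[match(grid$age_band, cfg$age_bands)]
  grid
}

#' Registry quality-indicator table
#'
#' One row per prefecture-year with the death-certificate-notification,
#' death-certificate-only and morphological-verification percentages and a
#' prefecture-level Gini coefficient. Quality improves over calendar time
#' (DCN% and DCO% fall, MV% rises), mirroring the gradual improvement seen
#' in long-running registries; the values are synthetic stand-ins, not
#' survey data.
#'
#' @param cfg A `scenario_config`.
#' @return A tibble with columns `prefecture`, `year`, `dcn_pct`,
#'   `dco_pct`, `mv_pct`, `gini`.
#' @export
generate_quality_table <- function(cfg) {
  validate_scenario(cfg)
  set.seed(substream_seed(cfg$seed, "misc"))
  grid <- tidyr::expand_grid(prefecture = cfg$prefectures, year = cfg$years)
  t <- grid$year - cfg$years[1]
  off <- (match(grid$prefecture, cfg$prefectures) - 1)
  grid$dcn_pct <- pmax(1, 24 - 0.60 * t + 1.0 * off + rnorm(nrow(grid), 0, 0.5))
  grid$dco_pct <- pmax(0.5, 14 - 0.45 * t + 0.7 * off + rnorm(nrow(grid), 0, 0.4))
  grid$mv_pct <- pmin(95, 71 + 0.28 * t - 0.8 * off + rnorm(nrow(grid), 0, 0.5))
  grid$gini <- pmin(0.9, pmax(0.1,
    0.29 + 0.012 * off + rnorm(nrow(grid), 0, 0.003)))
  grid
}

# representative ICD-O morphology code emitted for each true group
GROUP_CODES <- c(SMC = 8041L, SQC = 8070L, ADC = 8140L, LAC = 8012L,
                 other_nsclc = 8560L, other_unspec = 8000L)

#' Generate a synthetic registry
#'
#' Draws case counts per prefecture x year x sex x age-band x histology x
#' stage cell from independent Poisson distributions whose means follow the
#' scenario's baseline rates, histology mix, stage composition and
#' piecewise log-linear trends; expands counts to case records with
#' treatment, screening, quality and follow-up covariates; then applies the
#' two logistic MAR masking models. Masked histology is replaced by
#' nonspecific morphology code 8010 or 8046 (8046 never for true small-cell
#' disease, since that code excludes it); masked stage is labelled
#' "Unknown" or left blank. True small-cell cases masked as nonspecific are
#' always coded 8010. Cases whose true group is the other/unspecified
#' bucket are never masked: the nonspecific codes restrict the truth to the
#' five (8010) or four (8046) specific groups, so a masked record is by
#' construction one of those. The pre-masking values are returned in a
#' separate truth table so downstream recovery tests cannot leak.
#'
#' @param cfg A `scenario_config`.
#' @return A list with elements `records` (raw registry rows: morphology
#'   codes and stage strings, not yet recoded), `population`, `quality` and
#'   `truth` (case_id, true histology group, true stage, masking flags).
#' @export
generate_registry <- function(cfg) {
  validate_scenario(cfg)
  population <- generate_population(cfg)
  quality <- generate_quality_table(cfg)
  set.seed(substream_seed(cfg$seed, "registry"))

  bands <- cfg$age_bands
  nb <- length(bands)
  age_mid <- c(seq(2.5, 82.5, 5), 89)[seq_len(nb)]

  cells <- tidyr::expand_grid(
    prefecture = cfg$prefectures, year = cfg$years, sex = cfg$sex_levels,
    age_band = bands, histology = HIST_LEVELS, stage = STAGE_LEVELS
  )
  bi <- match(cells$age_band, bands)
  py <- rep_len(cfg$person_years, nb)[bi]
  base <- mapply(function(s, b) cfg$base_rates[[s]][b], cells$sex, bi)
  mix <- mapply(function(s, h) cfg$histology_mix[[s]][[h]],
                cells$sex, cells$histology)

  # stage composition: histology x year x band x stage array
  sp <- array(NA_real_, c(length(HIST_LEVELS), length(cfg$years), nb, 3),
              dimnames = list(HIST_LEVELS, cfg$years, bands, STAGE_LEVELS))
  for (h in HIST_LEVELS) {
    for (b in seq_len(nb)) {
      sp[h, , b, ] <- stage_probs(cfg, h, cfg$years, age_mid[b])
    }
  }
  stage_p <- sp[cbind(match(cells$histology, HIST_LEVELS),
                      match(cells$year, cfg$years), bi,
                      match(cells$stage, STAGE_LEVELS))]

  # trend factors: (sex, histology, stage) x year
  tf <- vector("list", 0)
  for (s in cfg$sex_levels) for (h in HIST_LEVELS) for (st in STAGE_LEVELS) {
    tf[[paste(s, h, st)]] <- trend_factor(cfg, s, h, st)
  }
  trend <- mapply(function(s, h, st, y) {
    tf[[paste(s, h, st)]][y]
  }, cells$sex, cells$histology, cells$stage, match(cells$year, cfg$years))

  mu <- py / 1e5 * base * mix * stage_p * trend
  stratum <- paste(cells$prefecture, cells$year, cells$sex, cells$age_band)
  if (any(tapply(mu, stratum, sum) > tapply(py, stratum, max))) {
    stop("configured rates imply more expected cases than person-years in ",
         "at least one stratum")
  }
  n_cell <- rpois(nrow(cells), mu)

  idx <- rep.int(seq_len(nrow(cells)), n_cell)
  rec <- cells[idx, ]
  n <- nrow(rec)
  rec$case_id <- sprintf("C%07d", seq_len(n))
  b <- match(rec$age_band, bands)
  lo <- (b - 1L) * 5L
  width <- ifelse(b == nb, 10L, 5L)   # 85+ spread over 85-94
  rec$age_years <- lo + floor(runif(n) * width)

  loc <- rec$stage == "localized"
  dist <- rec$stage == "distant"
  reg <- rec$stage == "regional"
  smc <- rec$histology == "SMC"
  age80 <- rec$age_years >= 80
  t_yr <- rec$year - cfg$years[1]

  rec$surgery <- runif(n) < plogis(-0.5 + 1.2 * loc - 1.5 * dist -
                                     0.8 * smc - 1.0 * age80)
  rec$radiotherapy <- runif(n) < plogis(-1.2 + 0.6 * reg + 0.4 * dist +
                                          0.5 * smc)
  rec$chemotherapy <- runif(n) < plogis(-1.2 + 1.2 * dist + 1.0 * smc -
                                          0.8 * age80)
  rec$laparoscopy <- runif(n) < ifelse(loc, 0.02, 0.002)
  rec$screening_detected <- runif(n) < plogis(-2.2 + 1.0 * loc +
                                                0.3 * (rec$year >= 2007))

  rec$dco_flag <- runif(n) < plogis(-3.0 + 0.6 * age80 + 0.5 * dist +
                                      0.5 * (t_yr < 8))
  rec$dcn_flag <- rec$dco_flag | runif(n) < 0.08
  rec$mv_flag <- !rec$dco_flag & runif(n) < 0.78
  rec$surgery[rec$dco_flag] <- FALSE
  rec$radiotherapy[rec$dco_flag] <- FALSE
  rec$chemotherapy[rec$dco_flag] <- FALSE
  rec$laparoscopy[rec$dco_flag] <- FALSE
  rec$screening_detected[rec$dco_flag] <- FALSE

  haz <- cfg$survival_spec[cbind(match(rec$stage, STAGE_LEVELS),
                                 match(rec$histology, HIST_LEVELS))]
  surv_t <- rexp(n, haz)
  cens <- cfg$censor_year - rec$year
  rec$obs_years <- pmin(surv_t, cens)
  rec$vital_status <- ifelse(surv_t <= cens, "dead", "alive")
  rec$obs_years[rec$dco_flag] <- 0
  rec$vital_status[rec$dco_flag] <- "dead"

  rec <- dplyr::left_join(rec, quality, by = c("prefecture", "year"))

  # MAR masking -------------------------------------------------------
  no_treat <- !(rec$surgery | rec$radiotherapy | rec$chemotherapy |
                  rec$laparoscopy)
  mask_eta <- function(mm) {
    mm$intercept + mm$female * (rec$sex == "female") + mm$age80 * age80 +
      mm$prefecture[rec$prefecture] + mm$year * t_yr +
      mm$no_treatment * no_treat + mm$obs_years * rec$obs_years +
      mm$dco * rec$dco_flag +
      (mm$distant %||% 0) * (rec$stage == "distant")   # MNAR misuse knob
  }
  p_h <- plogis(mask_eta(cfg$miss_histology))
  p_s <- plogis(mask_eta(cfg$miss_stage))
  hist_masked <- runif(n) < p_h & rec$histology != "other_unspec"
  stage_masked <- runif(n) < p_s

  code <- GROUP_CODES[rec$histology]
  to_8046 <- hist_masked & !smc & runif(n) < cfg$p_8046
  code[hist_masked] <- 8010L
  code[to_8046] <- 8046L
  rec$morphology_code <- unname(code)

  stage_raw <- c(localized = "Localized", regional = "Regional",
                 distant = "Distant")[rec$stage]
  unk <- stage_masked & runif(n) < cfg$p_unknown_stage
  stage_raw[stage_masked] <- ""
  stage_raw[unk] <- "Unknown"
  rec$stage_raw <- unname(stage_raw)

  truth <- tibble::tibble(
    case_id = rec$case_id, histology = rec$histology, stage = rec$stage,
    hist_masked = hist_masked, stage_masked = stage_masked
  )
  records <- tibble::as_tibble(rec[, c(
    "case_id", "prefecture", "year", "sex", "age_years", "age_band",
    "morphology_code", "stage_raw", "screening_detected", "surgery",
    "radiotherapy", "chemotherapy", "laparoscopy", "obs_years",
    "vital_status", "dco_flag", "dcn_flag", "mv_flag",
    "dcn_pct", "dco_pct", "mv_pct", "gini"
  )])
  names(records)[names(records) == "year"] <- "diag_year"
  list(records = records, population = population, quality = quality,
       truth = truth)
}
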