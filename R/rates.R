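#' Standard population weights
#'
#' Reads an age-band -> weight table and normalizes the weights to sum
#' to 1. The bundled default is a synthetic stand-in with a 1985-Japan-like
#' age structure (file `standard_population_1985_synthetic.csv`); swap in
#' the official table for real analyses — every computation is
#' weight-agnostic.
#'
#' @param path CSV with columns `age_band`, `population` (or `weight`).
#' @return A tibble with `age_band` and `weight` (summing to 1), with the
#'   source name as attribute `standard_name`.
#' @export
standard_population <- function(path = NULL) {
  path <- path %||% pkg_extdata("standard_population_1985_synthetic.csv")
  d <- tibble::as_tibble(read.csv(path, comment.char = "#"))
  w <- if ("weight" %in% names(d)) d$weight else d$population
  if (any(w <= 0)) stop("standard-population weights must be positive")
  out <- tibble::tibble(age_band = d$age_band, weight = w / sum(w))
  attr(out, "standard_name") <- basename(path)
  out
}

#' Directly age-standardized incidence rate
#'
#' `rate = 1e5 * sum(w_a d_a / n_a)` cases per 100,000 person-years, with
#' Poisson variance `1e10 * sum(w_a^2 d_a / n_a^2)`. Counts, denominators
#' and weights must cover the same age bands.
#'
#' @param counts Named (by age band) case counts `d_a`.
#' @param person_years Named person-years `n_a`, all positive.
#' @param standard A [standard_population()] table.
#' @return An object of class `rate_estimate`: list with `rate`,
#'   `variance`, `case_count` and per-band detail.
#' @export
asir <- function(counts, person_years, standard) {
  bands <- standard$age_band
  if (is.null(names(counts)) || is.null(names(person_years))) {
    if (length(counts) != length(bands) ||
        length(person_years) != length(bands)) {
      stop("unnamed counts/person_years must match the standard's bands")
    }
    names(counts) <- names(person_years) <- bands
  }
  if (!all(bands %in% names(counts)) ||
      !all(bands %in% names(person_years))) {
    stop("missing age bands: ",
         paste(setdiff(bands, intersect(names(counts),
                                        names(person_years))),
               collapse = ", "))
  }
  d <- as.numeric(counts[bands])
  n <- as.numeric(person_years[bands])
  if (any(d < 0)) stop("negative case counts")
  if (any(n <= 0)) stop("person-years must be positive")
  w <- standard$weight
  structure(list(
    rate = 1e5 * sum(w * d / n),
    variance = 1e10 * sum(w^2 * d / n^2),
    case_count = sum(d),
    detail = tibble::tibble(age_band = bands, d = d, n = n, w = w)
  ), class = "rate_estimate")
}

#' Gamma confidence interval for a standardized rate
#'
#' Fay-Feuer gamma interval: the lower bound is the `alpha/2` gamma
#' quantile with shape `rate^2/variance` and scale `variance/rate`; the
#' upper bound adds a continuity adjustment term to the rate and its
#' square to the variance before taking the `1 - alpha/2` quantile. The
#' original method uses the maximum over age bands of the per-band rate
#' contribution of one case (`1e5 * w_a / n_a`); Tiwari's modification —
#' the default — uses the mean instead, which is less conservative. A zero
#' rate gets a lower bound of exactly 0.
#'
#' @param estimate A `rate_estimate` from [asir()], optionally with its
#'   `variance` replaced by a Rubin-pooled total variance.
#' @param alpha Two-sided error level (default 0.05).
#' @param method "tiwari" (mean adjustment) or "fay-feuer" (maximum).
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
gamma_ci <- function(estimate, alpha = 0.05,
                     method = c("tiwari", "fay-feuer")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  x <- estimate$rate
  v <- estimate$variance
  if (v < 0) stop("variance must be nonnegative")
  wn <- 1e5 * estimate$detail$w / estimate$detail$n
  adj <- if (method == "tiwari") mean(wn) else max(wn)
  lo <- if (x <= 0 || v <= 0) 0 else qgamma(alpha / 2, shape = x^2 / v,
                                            scale = v / x)
  hi <- qgamma(1 - alpha / 2, shape = (x + adj)^2 / (v + adj^2),
               scale = (v + adj^2) / (x + adj))
  c(ci_low = lo, ci_high = hi)
}

# counts by age band for the records matching a stratifier
band_counts <- function(records, bands, sex = NULL, histology = NULL,
                        stage = NULL, year = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(sex)) keep <- keep & records$sex == sex
  if (!is.null(year)) keep <- keep & records$diag_year == year
  if (!is.null(histology)) {
    keep <- keep & !is.na(records$histology_group) &
      records$histology_group == histology
  }
  if (!is.null(stage)) {
    keep <- keep & !is.na(records$stage) & records$stage == stage
  }
  tab <- table(factor(records$age_band[keep], levels = bands))
  setNames(as.numeric(tab), bands)
}

person_years_by_band <- function(population, bands, sex, year) {
  sub <- population[population$sex == sex & population$year == year, ]
  agg <- tapply(sub$person_years, factor(sub$age_band, levels = bands), sum)
  setNames(as.numeric(agg), bands)
}

#' Annual age-standardized rate series, pooled across imputations
#'
#' For every diagnosis year, computes the per-imputation ASIR of the
#' requested stratum, pools point estimates and Poisson variances by
#' Rubin's rules, and attaches a gamma interval computed with the pooled
#' total variance in place of the single-sample variance. A complete-case
#' series (cases whose histology/stage was observed, over the same
#' denominators) is computed alongside for sensitivity comparison.
#'
#' @param stack An `imputed_stack` from [multiple_impute()], or a plain
#'   list of completed record tibbles.
#' @param population Person-year table from [generate_population()] (or
#'   the same layout for external data).
#' @param standard A [standard_population()] table.
#' @param sex Stratum sex (required; rates are sex-specific).
#' @param histology,stage Optional stratum labels; NULL means all.
#' @param alpha CI level for the gamma intervals.
#' @param ci_method Passed to [gamma_ci()].
#' @return A tibble of class `rate_series`: one row per year and source
#'   (`imputed` / `complete_case`) with rate, variance (pooled total `T`
#'   for the imputed rows), within/between components, CI bounds and case
#'   counts.
#' @export
pooled_rate_series <- function(stack, population, standard, sex,
                               histology = NULL, stage = NULL,
                               alpha = 0.05, ci_method = "tiwari") {
  imps <- if (inherits(stack, "imputed_stack")) stack$imputations else stack
  m <- length(imps)
  if (m < 1) stop("empty imputation stack")
  bands <- standard$age_band
  years <- sort(unique(population$year))
  original <- if (inherits(stack, "imputed_stack")) {
    orig <- imps[[1]]
    orig$histology_group[stack$miss_histology] <- NA
    orig$stage[stack$miss_stage] <- NA
    orig
  } else NULL

  rows <- lapply(years, function(y) {
    n_a <- person_years_by_band(population, bands, sex, y)
    ests <- lapply(imps, function(im) {
      asir(band_counts(im, bands, sex, histology, stage, y), n_a, standard)
    })
    rates <- vapply(ests, function(e) e$rate, numeric(1))
    vars <- vapply(ests, function(e) e$variance, numeric(1))
    pooled <- if (m >= 2) rubin_pool(rates, vars) else
      list(point = rates, W = vars, B = 0, T = vars, df = Inf)
    est <- ests[[1]]
    est$rate <- pooled$point
    est$variance <- pooled$T
    ci <- gamma_ci(est, alpha, ci_method)
    out <- tibble::tibble(
      year = y, source = "imputed", rate = pooled$point,
      variance = pooled$T, W = pooled$W, B = pooled$B,
      ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
      n_cases = mean(vapply(ests, function(e) e$case_count, numeric(1))),
      empty = pooled$point == 0
    )
    if (!is.null(original)) {
      ecc <- asir(band_counts(original, bands, sex, histology, stage, y),
                  n_a, standard)
      ci_cc <- gamma_ci(ecc, alpha, ci_method)
      out <- dplyr::bind_rows(out, tibble::tibble(
        year = y, source = "complete_case", rate = ecc$rate,
        variance = ecc$variance, W = ecc$variance, B = 0,
        ci_low = ci_cc[["ci_low"]], ci_high = ci_cc[["ci_high"]],
        n_cases = ecc$case_count, empty = ecc$rate == 0
      ))
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  out$sex <- sex
  out$histology <- histology %||% "all"
  out$stage <- stage %||% "all"
  structure(out, class = c("rate_series", class(out)))
}

#' Female-to-male incidence-rate-ratio series
#'
#' `IRR = R_f / R_m` per year, with the confidence interval computed on
#' the log scale by the delta method using the (pooled) variances of the
#' two rates: `exp(log irr +/- z sqrt(T_f/R_f^2 + T_m/R_m^2))`. Years in
#' which either rate is zero are flagged undefined.
#'
#' @param female,male `rate_series` for the same stratum definition and
#'   years (the `imputed` rows are used).
#' @param alpha Two-sided error level.
#' @return A tibble with year, irr, ci_low, ci_high, defined.
#' @export
irr_series <- function(female, male, alpha = 0.05) {
  f <- female[female$source == "imputed", ]
  m <- male[male$source == "imputed", ]
  if (!identical(f$year, m$year)) stop("female and male series differ in years")
  z <- qnorm(1 - alpha / 2)
  defined <- f$rate > 0 & m$rate > 0
  irr <- ifelse(defined, f$rate / m$rate, NA_real_)
  se_log <- ifelse(defined,
                   sqrt(f$variance / f$rate^2 + m$variance / m$rate^2),
                   NA_real_)
  tibble::tibble(
    year = f$year, irr = irr,
    ci_low = exp(log(irr) - z * se_log),
    ci_high = exp(log(irr) + z * se_log),
    defined = defined
  )
}
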