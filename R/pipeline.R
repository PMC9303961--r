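#' Write / read a registry table with a seed header
#'
#' Tabular artifacts carry the generating seed in a leading comment line
#' so every file is regenerable from configuration alone.
#'
#' @param x Data frame to write.
#' @param path Output CSV path.
#' @param seed Integer seed recorded in the header.
#' @export
write_seeded_csv <- function(x, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed: ", seed), con)
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seeded_csv
#' @export
read_seeded_csv <- function(path) {
  tibble::as_tibble(read.csv(path, comment.char = "#"))
}

format_estimate <- function(est, lo, hi, digits = 1) {
  sprintf("%.*f (%.*f to %.*f)", digits, est, digits, lo, digits, hi)
}

#' Trend summary for one rate series
#'
#' Runs permutation joinpoint selection on a `rate_series` (one source)
#' and formats the AAPC and per-segment APCs the way trend tables are
#' conventionally displayed: "x.x (lo to hi)".
#'
#' @param series A `rate_series` tibble (from [pooled_rate_series()]).
#' @param source "imputed" or "complete_case".
#' @param k_max,n_perm,alpha,seed Passed to [permutation_select()].
#' @return A one-row tibble with the selected model in a list column.
#' @export
trend_summary <- function(series, source = "imputed", k_max = 2L,
                          n_perm = 999L, alpha = 0.05, seed = 1L) {
  s <- series[series$source == source, ]
  ti <- trend_input(s$year, s$rate, sqrt(pmax(s$variance, 1e-12)))
  model <- permutation_select(ti, k_max = k_max, n_perm = n_perm,
                              alpha = alpha, seed = seed)
  a <- aapc(model)
  segs <- apc(model)
  tibble::tibble(
    sex = s$sex[1], histology = s$histology[1], stage = s$stage[1],
    source = source, k = model$k,
    tau = paste(model$tau, collapse = ";"),
    aapc = a$aapc, aapc_low = a$ci_low, aapc_high = a$ci_high,
    aapc_fmt = format_estimate(a$aapc, a$ci_low, a$ci_high),
    apc_fmt = paste(sprintf("%d-%d: %s", segs$start, segs$end,
                            format_estimate(segs$apc, segs$ci_low,
                                            segs$ci_high)),
                    collapse = "; "),
    model = list(model)
  )
}

default_series <- function() {
  tidyr::expand_grid(
    sex = c("male", "female"),
    key = c("all", "SMC", "SQC", "ADC", "localized", "regional", "distant")
  ) |>
    dplyr::mutate(
      histology = ifelse(.data$key %in% HIST_LEVELS, .data$key, NA),
      stage = ifelse(.data$key %in% STAGE_LEVELS, .data$key, NA)
    ) |>
    dplyr::select(-"key")
}

#' Run the full analysis pipeline
#'
#' Generate (or accept) a registry, recode it, tabulate the descriptive
#' margins, multiply impute histology and stage, compute Rubin-pooled and
#' complete-case age-standardized rate series for the requested strata,
#' run joinpoint trend selection on both, compute female-to-male
#' incidence-rate-ratio series for every stratum available in both sexes,
#' run the survival-based imputation validation and the missingness
#' diagnostics, and (optionally) write everything plus a manifest to an
#' output directory.
#'
#' @param scenario A `scenario_config`; its seed is replaced by `seed`.
#' @param imp_spec An [imputation_spec()]; its seed is replaced by `seed`.
#' @param standard A [standard_population()] table (bands must match the
#'   scenario's).
#' @param series Data frame of strata (`sex`, `histology`, `stage`, NA =
#'   marginal) to compute rate series for.
#' @param k_max,n_perm,alpha Joinpoint selection settings.
#' @param out_dir Output directory; NULL skips writing.
#' @param seed Global seed fanned out to per-stage substreams.
#' @return A list with all intermediate and final artifacts plus a
#'   manifest (seed, row counts, file hashes when written).
#' @export
run_pipeline <- function(scenario = default_scenario(),
                         imp_spec = imputation_spec(),
                         standard = scenario_standard(scenario),
                         series = default_series(),
                         k_max = 2L, n_perm = 999L, alpha = 0.05,
                         out_dir = NULL, seed = 1L) {
  scenario$seed <- as.integer(seed)
  imp_spec$seed <- as.integer(seed)
  stage_log <- list()
  log_stage <- function(name, n_in, n_out) {
    stage_log[[name]] <<- tibble::tibble(stage = name, rows_in = n_in,
                                         rows_out = n_out)
  }

  gen <- generate_registry(scenario)
  log_stage("generate", NA_integer_, nrow(gen$records))
  rec <- recode_stage(recode_histology(gen$records))
  log_stage("recode", nrow(gen$records), nrow(rec))

  tabs <- list(
    histology = tabulate_cases(rec, "histology"),
    stage = tabulate_cases(rec, "stage"),
    histology_stage = tabulate_cases(rec, "histology_stage")
  )

  stack <- multiple_impute(rec, imp_spec)
  log_stage("impute", nrow(rec), nrow(stack$imputations[[1]]))

  rate_series <- list()
  trends <- list()
  for (i in seq_len(nrow(series))) {
    h <- series$histology[i]
    st <- series$stage[i]
    key <- paste(series$sex[i], ifelse(is.na(h), "all", h),
                 ifelse(is.na(st), "all", st), sep = ".")
    rs <- pooled_rate_series(stack, gen$population, standard,
                             sex = series$sex[i],
                             histology = if (is.na(h)) NULL else h,
                             stage = if (is.na(st)) NULL else st)
    rate_series[[key]] <- rs
    for (src in c("imputed", "complete_case")) {
      trends[[paste(key, src, sep = ".")]] <- trend_summary(
        rs, src, k_max = k_max, n_perm = n_perm, alpha = alpha,
        seed = substream_seed(seed, "trends") + i)
    }
  }
  trend_table <- dplyr::bind_rows(trends)[, c(
    "sex", "histology", "stage", "source", "k", "tau", "aapc",
    "aapc_low", "aapc_high", "aapc_fmt", "apc_fmt")]

  # FM-IRR for every stratum computed in both sexes
  irr <- list()
  fkeys <- grep("^female\\.", names(rate_series), value = TRUE)
  for (fk in fkeys) {
    mk <- sub("^female\\.", "male.", fk)
    if (mk %in% names(rate_series)) {
      irr[[sub("^female\\.", "", fk)]] <-
        irr_series(rate_series[[fk]], rate_series[[mk]])
    }
  }

  validation <- validate_imputation(stack, rec)
  diagnostics <- missingness_diagnostics(rec)

  manifest <- list(seed = seed, n_records = nrow(rec),
                   m = imp_spec$m, n_cycles = imp_spec$n_cycles,
                   stage_log = dplyr::bind_rows(stage_log))
  result <- list(
    scenario = scenario, records = rec, population = gen$population,
    quality = gen$quality, truth = gen$truth, tabulations = tabs,
    stack = stack, rate_series = rate_series, trend_table = trend_table,
    irr = irr, validation = validation, diagnostics = diagnostics,
    manifest = manifest
  )
  if (!is.null(out_dir)) {
    result$manifest$files <- write_pipeline_outputs(result, out_dir, seed)
  }
  result
}

#' Standard population matched to a scenario's age bands
#'
#' Restricts (and renormalizes) the bundled standard-population table to
#' the scenario's age bands.
#'
#' @param scenario A `scenario_config`.
#' @param path Optional alternative standard-population CSV.
#' @return A standard-population tibble.
#' @export
scenario_standard <- function(scenario, path = NULL) {
  std <- standard_population(path)
  keep <- std$age_band %in% scenario$age_bands
  if (!any(keep)) stop("standard population shares no age bands with the ",
                       "scenario")
  out <- std[keep, ]
  out$weight <- out$weight / sum(out$weight)
  out
}

#' Read a pipeline run configuration
#'
#' YAML file with any of: `seed`, `person_years`, `m`, `n_cycles`,
#' `k_max`, `n_perm`, `alpha`, `out_dir`. Missing fields fall back to the
#' package defaults. Used by the command-line wrapper; programmatic users
#' can call [run_pipeline()] directly.
#'
#' @param path YAML file path.
#' @return A named list of run settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(seed = 1L, person_years = 21500, m = 20L, n_cycles = 5L,
                   k_max = 2L, n_perm = 999L, alpha = 0.05,
                   out_dir = "registrytrends-output")
  utils::modifyList(defaults, cfg[names(cfg) %in% names(defaults)])
}

write_pipeline_outputs <- function(result, out_dir, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wr <- function(x, name) {
    p <- file.path(out_dir, name)
    write_seeded_csv(x, p, seed)
    paths <<- c(paths, p)
  }
  wr(result$records, "records.csv")
  wr(result$population, "population.csv")
  wr(result$quality, "quality.csv")
  for (m in names(result$tabulations)) {
    wr(tibble::as_tibble(result$tabulations[[m]]),
       paste0("tabulation_", m, ".csv"))
  }
  rs <- dplyr::bind_rows(result$rate_series)
  wr(rs, "rate_series.csv")
  wr(result$trend_table, "trend_table.csv")
  if (length(result$irr)) {
    irr_all <- dplyr::bind_rows(result$irr, .id = "stratum")
    wr(irr_all, "irr_series.csv")
  }
  wr(result$validation$strata, "validation_strata.csv")
  wr(result$diagnostics, "missingness_diagnostics.csv")
  manifest <- result$manifest
  manifest$stage_log <- NULL
  hashes <- tools::md5sum(paths)
  names(hashes) <- basename(paths)
  manifest$hashes <- as.list(hashes)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  c(paths, mp)
}
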