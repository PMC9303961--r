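#' Morphology code lookup table
#'
#' Maps ICD-O morphology codes to the six histology groups. The two
#' nonspecific codes carry candidate sets instead of a group: 8010
#' (carcinoma NOS) restricts the truth to the five specific groups
#' (small-cell through other non-small-cell) and 8046 (non-small-cell
#' carcinoma) to the four non-small-cell specific groups. The bundled
#' default is a minimal editable table at the six-group resolution the
#' analysis needs, not a full ICD-O dictionary; extend the CSV to cover
#' additional codes.
#'
#' @param path Optional path to a CSV with columns `code`, `group`,
#'   `candidates` (pipe-separated). Defaults to the bundled table.
#' @return A tibble with columns `code` (integer), `group` (character or
#'   NA for nonspecific codes) and `candidates` (character, pipe-separated
#'   candidate groups, empty for specific codes).
#' @export
read_morphology_map <- function(path = NULL) {
  path <- path %||% pkg_extdata("morphology_map.csv")
  map <- tibble::as_tibble(read.csv(path, comment.char = "#",
                                    colClasses = c("integer", "character",
                                                   "character")))
  stopifnot(all(c("code", "group", "candidates") %in% names(map)))
  map$group[map$group == ""] <- NA_character_
  if (anyDuplicated(map$code)) stop("morphology map has duplicated codes")
  bad <- is.na(map$group) & map$candidates == ""
  if (any(bad)) stop("codes map to neither a group nor a candidate set: ",
                     paste(map$code[bad], collapse = ", "))
  map
}

#' @rdname read_morphology_map
#' @export
default_morphology_map <- function() read_morphology_map()

#' Recode morphology codes into histology groups
#'
#' Fills `histology_group` and `restriction` from `morphology_code` using
#' a morphology map. Records with a nonspecific code get an absent group
#' and a non-empty candidate set; all other records get their group and an
#' empty restriction. Recoding is idempotent: both columns are recomputed
#' from the code.
#'
#' @param records Registry records with a `morphology_code` column.
#' @param map A morphology map from [read_morphology_map()].
#' @return `records` with `histology_group` (character, NA when absent)
#'   and `restriction` (pipe-separated candidate groups, "" when none).
#' @export
recode_histology <- function(records, map = default_morphology_map()) {
  i <- match(records$morphology_code, map$code)
  if (anyNA(i)) {
    stop("unmapped morphology codes: ",
         paste(sort(unique(records$morphology_code[is.na(i)])),
               collapse = ", "))
  }
  records$histology_group <- map$group[i]
  records$restriction <- map$candidates[i]
  records
}

#' Recode raw stage strings
#'
#' Normalizes the documented stage vocabulary ("Localized", "Regional",
#' "Distant", "Unknown", empty string or NA) into the analysis categories.
#' Unknown and unreported stages are both treated as absent but keep their
#' label in `stage_unknown_kind` for tabulation.
#'
#' @param records Registry records with a `stage_raw` column.
#' @return `records` with `stage` (localized/regional/distant or NA) and
#'   `stage_unknown_kind` (none/unknown/missing).
#' @export
recode_stage <- function(records) {
  raw <- records$stage_raw
  raw[is.na(raw)] <- ""
  known <- c(Localized = "localized", Regional = "regional",
             Distant = "distant")
  ok <- raw %in% c(names(known), "Unknown", "")
  if (!all(ok)) {
    stop("unrecognized stage strings: ",
         paste(sort(unique(raw[!ok])), collapse = ", "))
  }
  records$stage <- unname(known[raw])
  records$stage_unknown_kind <- ifelse(raw %in% names(known), "none",
                                       ifelse(raw == "Unknown", "unknown",
                                              "missing"))
  records
}

default_periods <- function() {
  list("1993-1999" = 1993:1999, "2000-2004" = 2000:2004,
       "2005-2009" = 2005:2009, "2010-2015" = 2010:2015)
}

period_of <- function(years, periods) {
  lab <- rep(NA_character_, length(years))
  for (p in names(periods)) lab[years %in% periods[[p]]] <- p
  if (anyNA(lab)) {
    stop("diagnosis years outside all periods: ",
         paste(sort(unique(years[is.na(lab)])), collapse = ", "))
  }
  factor(lab, levels = names(periods))
}

#' Tabulate cases by sex and period of diagnosis
#'
#' Counts and row percentages (within sex x period) for one of three
#' margins:
#' \describe{
#'   \item{histology}{the six histology groups plus the two nonspecific
#'     codes as separate rows (this partitions the cases), with a pooled
#'     "nonspecific" memo row;}
#'   \item{stage}{localized/regional/distant/unknown/missing (partition)
#'     plus a pooled "unknown_missing" memo row;}
#'   \item{histology_stage}{stage distribution within each histology
#'     supergroup (SMC, SQC, ADC, a combined other group, nonspecific
#'     codes), with percentages within the supergroup.}
#' }
#' Memo rows repeat cases already counted in the partition and are flagged
#' so that conservation checks can exclude them. Percentages are computed
#' on exact counts and rounded only for display.
#'
#' @param records Recoded registry records.
#' @param margin One of "histology", "stage", "histology_stage".
#' @param periods Named list of diagnosis-year vectors; defaults to the
#'   four periods 1993-1999, 2000-2004, 2005-2009, 2010-2015. Every record
#'   must fall in a period.
#' @return A tibble of class `case_tabulation` with columns `sex`,
#'   `period` (including "overall"), grouping columns, `n`, `pct`, `memo`.
#' @export
tabulate_cases <- function(records,
                           margin = c("histology", "stage",
                                      "histology_stage"),
                           periods = default_periods()) {
  margin <- match.arg(margin)
  if (margin != "stage" && !"histology_group" %in% names(records)) {
    stop("records must be recoded first (see recode_histology)")
  }
  if (margin != "histology" && !"stage" %in% names(records)) {
    stop("records must be recoded first (see recode_stage)")
  }
  rec <- records
  rec$period <- period_of(rec$diag_year, periods)

  if (margin == "histology") {
    cat_lab <- ifelse(rec$morphology_code == 8010, "code_8010",
                      ifelse(rec$morphology_code == 8046, "code_8046",
                             rec$histology_group))
    levels_ <- c(HIST_LEVELS, "code_8010", "code_8046")
    memo_of <- list(nonspecific = c("code_8010", "code_8046"))
  } else if (margin == "stage") {
    cat_lab <- ifelse(!is.na(rec$stage), rec$stage, rec$stage_unknown_kind)
    levels_ <- c(STAGE_LEVELS, "unknown", "missing")
    memo_of <- list(unknown_missing = c("unknown", "missing"))
  } else {
    super <- ifelse(is.na(rec$histology_group), "nonspecific",
                    ifelse(rec$histology_group %in% c("SMC", "SQC", "ADC"),
                           rec$histology_group, "other_combined"))
    cat_lab <- ifelse(!is.na(rec$stage), rec$stage, "unknown_missing")
    levels_ <- c(STAGE_LEVELS, "unknown_missing")
  }

  count_cells <- function(df, extra_group = NULL) {
    g <- c("sex", "period", extra_group, "category")
    out <- dplyr::count(df, dplyr::across(dplyr::all_of(g)), .drop = FALSE)
    out
  }

  if (margin == "histology_stage") {
    rec$super <- factor(super, levels = c("SMC", "SQC", "ADC",
                                          "other_combined", "nonspecific"))
    rec$category <- factor(cat_lab, levels = levels_)
    both <- dplyr::bind_rows(
      count_cells(rec, "super"),
      count_cells(dplyr::mutate(rec, period = factor("overall")), "super")
    )
    both <- dplyr::group_by(both, .data$sex, .data$period, .data$super)
    both <- dplyr::mutate(both, pct = 100 * .data$n / sum(.data$n))
    both <- dplyr::ungroup(both)
    both$memo <- FALSE
  } else {
    rec$category <- factor(cat_lab, levels = levels_)
    both <- dplyr::bind_rows(
      count_cells(rec),
      count_cells(dplyr::mutate(rec, period = factor("overall")))
    )
    both <- dplyr::group_by(both, .data$sex, .data$period)
    both <- dplyr::mutate(both, total = sum(.data$n))
    both <- dplyr::ungroup(both)
    memo <- dplyr::bind_rows(lapply(names(memo_of), function(m) {
      sub <- both[both$category %in% memo_of[[m]], ]
      agg <- dplyr::summarise(dplyr::group_by(sub, .data$sex, .data$period),
                              n = sum(.data$n), total = .data$total[1],
                              .groups = "drop")
      agg$category <- m
      agg
    }))
    both$memo <- FALSE
    memo$memo <- TRUE
    both <- dplyr::bind_rows(both, memo)
    both$pct <- 100 * both$n / both$total
    both$total <- NULL
  }
  both$pct[is.nan(both$pct)] <- 0
  structure(both, class = c("case_tabulation", class(both)),
            margin = margin, n_records = nrow(records))
}

#' Packaged descriptive-count fixture
#'
#' Expands the bundled descriptive count table (histology and stage
#' margins by sex and period for a 62,870-case lung-cancer registry
#' series, 1993-2015) into pseudo-records so that tabulation arithmetic
#' (shares, pooled unknown/missing, nonspecific totals) can be checked
#' against published percentages by independent counting. The two margins
#' are expanded separately: `histology` rows carry morphology codes,
#' `stage` rows carry stage strings.
#'
#' @return A list with recoded record tibbles `histology` and `stage`.
#' @export
table1_fixture <- function() {
  path <- pkg_extdata("table1_counts.csv")
  counts <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  periods <- default_periods()
  start_year <- vapply(periods, min, numeric(1))
  expand <- function(margin_name) {
    d <- counts[counts$margin == margin_name, ]
    idx <- rep.int(seq_len(nrow(d)), d$count)
    tibble::tibble(
      case_id = sprintf("F%06d", seq_along(idx)),
      sex = d$sex[idx],
      diag_year = as.integer(start_year[d$period[idx]]),
      category = d$category[idx]
    )
  }
  hist_rec <- expand("histology")
  code_map <- c(GROUP_CODES, code_8010 = 8010L, code_8046 = 8046L)
  hist_rec$morphology_code <- unname(code_map[hist_rec$category])
  hist_rec$category <- NULL
  hist_rec <- recode_histology(hist_rec)

  stage_rec <- expand("stage")
  stage_map <- c(localized = "Localized", regional = "Regional",
                 distant = "Distant", unknown = "Unknown", missing = "")
  stage_rec$stage_raw <- unname(stage_map[stage_rec$category])
  stage_rec$category <- NULL
  stage_rec <- recode_stage(stage_rec)
  list(histology = hist_rec, stage = stage_rec)
}
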