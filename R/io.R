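parse_dates <- function(x) {
  if (inherits(x, "Date")) return(x)
  if (inherits(x, "POSIXt")) return(as.Date(x))
  out <- suppressWarnings(lubridate::parse_date_time(
    as.character(x), orders = c("Ymd HMS", "Ymd HM", "Ymd"), quiet = TRUE))
  as.Date(out)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("'%s' is missing required column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "adheretraj_schema_error")
  }
}

finalize_read <- function(good, rejects, path, max_reject_frac = 0.1) {
  n_total <- nrow(good) + nrow(rejects)
  if (n_total > 0 && nrow(rejects) / n_total > max_reject_frac) {
    abort(sprintf(
      "'%s': %d of %d rows rejected (%s); above the %.0f%% abort threshold.",
      path, nrow(rejects), n_total,
      paste(unique(rejects$reason), collapse = "; "),
      100 * max_reject_frac), class = "adheretraj_schema_error")
  }
  if (nrow(rejects) > 0) {
    message(sprintf("%s: quarantined %d of %d rows (%s)", basename(path),
                    nrow(rejects), n_total,
                    paste(unique(rejects$reason), collapse = "; ")))
  }
  attr(good, "rejects") <- rejects
  good
}

read_csv_quiet <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'", path),
          class = "adheretraj_schema_error")
  }
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Read and validate trough-level records
#'
#' Expects a UTF-8 CSV with header `patient_id, date, level_ng_ml` (`#`
#' lines are treated as comments). Dates are accepted in ISO-8601 with or
#' without a time component. Row-level violations (unparseable date,
#' non-positive or non-numeric level, missing id) are quarantined — kept in
#' the `rejects` attribute with a reason, and written to `rejects_path` if
#' given — rather than failing the read; more than 10% rejected rows or a
#' missing required column aborts.
#'
#' @param path CSV path.
#' @param rejects_path Optional path to write quarantined rows.
#' @return Tibble `patient_id`, `date` (Date), `level_ng_ml` (double), with
#'   attribute `rejects`.
#' @export
read_troughs <- function(path, rejects_path = NULL) {
  raw <- read_csv_quiet(path)
  require_columns(raw, c("patient_id", "date", "level_ng_ml"), path)
  parsed <- raw %>%
    mutate(.date = parse_dates(.data$date),
           .level = suppressWarnings(as.numeric(.data$level_ng_ml)),
           reason = dplyr::case_when(
             is.na(.data$patient_id) | .data$patient_id == "" ~
               "missing patient id",
             is.na(.date) ~ "unparseable date",
             is.na(.level) ~ "non-numeric level",
             .level <= 0 ~ "nonpositive level",
             TRUE ~ NA_character_
           ))
  rejects <- parsed %>% filter(!is.na(.data$reason)) %>%
    select(dplyr::all_of(names(raw)), "reason")
  good <- parsed %>% filter(is.na(.data$reason)) %>%
    transmute(patient_id = .data$patient_id, date = .data$.date,
              level_ng_ml = .data$.level)
  if (!is.null(rejects_path) && nrow(rejects) > 0) {
    readr::write_csv(rejects, rejects_path)
  }
  finalize_read(good, rejects, path)
}

#' Read and validate the patient registry
#'
#' Expects columns `patient_id, transplant_date, organ` (plus optional
#' demographics: `sex`, `race`, `ethnicity`, `insurance`, `life_support`,
#' `functional_status`). Organ must be one of liver/kidney/heart and
#' insurance one of public/private where present; violating rows are
#' quarantined.
#'
#' @inheritParams read_troughs
#' @return Tibble with attribute `rejects`.
#' @export
read_patients <- function(path, rejects_path = NULL) {
  raw <- read_csv_quiet(path)
  require_columns(raw, c("patient_id", "transplant_date", "organ"), path)
  parsed <- raw %>%
    mutate(.date = parse_dates(.data$transplant_date),
           reason = dplyr::case_when(
             is.na(.data$patient_id) | .data$patient_id == "" ~
               "missing patient id",
             is.na(.date) ~ "unparseable transplant date",
             !(.data$organ %in% c("liver", "kidney", "heart")) ~
               "organ outside {liver, kidney, heart}",
             TRUE ~ NA_character_
           ))
  if ("insurance" %in% names(parsed)) {
    parsed <- parsed %>%
      mutate(reason = if_else(
        is.na(.data$reason) &
          !(.data$insurance %in% c("public", "private")),
        "insurance outside {public, private}", .data$reason))
  }
  rejects <- parsed %>% filter(!is.na(.data$reason)) %>%
    select(dplyr::all_of(names(raw)), "reason")
  good <- parsed %>% filter(is.na(.data$reason)) %>%
    mutate(transplant_date = .data$.date) %>%
    select(-".date", -"reason")
  for (col in intersect(c("life_support"), names(good))) {
    good[[col]] <- as.integer(good[[col]])
  }
  for (col in intersect(c("functional_status"), names(good))) {
    good[[col]] <- as.numeric(good[[col]])
  }
  if (!is.null(rejects_path) && nrow(rejects) > 0) {
    readr::write_csv(rejects, rejects_path)
  }
  finalize_read(good, rejects, path)
}

#' Read and validate per-patient-year outcome records
#'
#' Expects columns `patient_id, post_tx_year, lar_hosp` with `lar_hosp` in
#' \{0, 1\} and `post_tx_year` a positive integer; violating rows are
#' quarantined.
#'
#' @inheritParams read_troughs
#' @return Tibble with attribute `rejects`.
#' @export
read_outcomes <- function(path, rejects_path = NULL) {
  raw <- read_csv_quiet(path)
  require_columns(raw, c("patient_id", "post_tx_year", "lar_hosp"), path)
  parsed <- raw %>%
    mutate(.year = suppressWarnings(as.integer(.data$post_tx_year)),
           .lar = suppressWarnings(as.integer(.data$lar_hosp)),
           reason = dplyr::case_when(
             is.na(.data$patient_id) | .data$patient_id == "" ~
               "missing patient id",
             is.na(.year) | .year < 1 ~ "invalid post-transplant year",
             !(.lar %in% c(0L, 1L)) ~ "lar_hosp outside {0, 1}",
             TRUE ~ NA_character_
           ))
  rejects <- parsed %>% filter(!is.na(.data$reason)) %>%
    select(dplyr::all_of(names(raw)), "reason")
  good <- parsed %>% filter(is.na(.data$reason)) %>%
    transmute(patient_id = .data$patient_id, post_tx_year = .data$.year,
              lar_hosp = .data$.lar)
  if (!is.null(rejects_path) && nrow(rejects) > 0) {
    readr::write_csv(rejects, rejects_path)
  }
  finalize_read(good, rejects, path)
}

#' Write a tibble as CSV with a provenance comment header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param header Named character/numeric vector written as `# name: value`
#'   comment lines (seeds, config hash).
#' @return `path`, invisibly.
#' @export
write_csv_with_header <- function(df, path, header = NULL) {
  lines <- character()
  if (length(header) > 0) {
    lines <- sprintf("# %s: %s", names(header), as.character(header))
  }
  writeLines(lines, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `troughs.csv`, `patients.csv`, `outcomes.csv`, `truth.csv` into
#' `dir`, each with a `# seed:` comment header, in the schemas read back by
#' [read_troughs()], [read_patients()], [read_outcomes()].
#'
#' @param cohort A [synth_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(seed = cohort$config$seed, generator = "adheretraj::synth_cohort")
  write_csv_with_header(cohort$troughs, file.path(dir, "troughs.csv"), hdr)
  write_csv_with_header(cohort$patients, file.path(dir, "patients.csv"), hdr)
  write_csv_with_header(cohort$outcomes, file.path(dir, "outcomes.csv"), hdr)
  write_csv_with_header(cohort$truth, file.path(dir, "truth.csv"), hdr)
  invisible(dir)
}
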