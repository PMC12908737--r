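#' MLVI of a single window of trough levels
#'
#' The medication level variability index for one window is the sample
#' standard deviation (divisor n-1) of the tacrolimus levels in that window.
#' Windows with fewer than 3 troughs carry no MLVI and return `NA`.
#'
#' @param levels Numeric vector of tacrolimus levels, ng/mL; all must be
#'   positive.
#' @param divisor `"n-1"` (sample SD, default) or `"n"` (population SD).
#' @return The MLVI (SD units of ng/mL), or `NA_real_` if fewer than 3
#'   levels were supplied.
#' @examples
#' mlvi_window(c(6, 8, 10)) # 2
#' mlvi_window(c(5, 9))     # NA: too few troughs
#' @export
mlvi_window <- function(levels, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  bad <- which(!is.finite(levels) | levels <= 0)
  if (length(bad) > 0) {
    abort(sprintf("Non-positive or non-finite trough level at position %d (%s).",
                  bad[1], format(levels[bad[1]])),
          class = "adheretraj_data_error")
  }
  if (length(levels) < 3) return(NA_real_)
  s <- sd(levels)
  if (divisor == "n") s <- s * sqrt((length(levels) - 1) / length(levels))
  s
}

new_mlvi_panel <- function(cells, patient_ids, cadence, n_occasions) {
  structure(
    cells,
    patient_ids = patient_ids,
    cadence = cadence,
    n_occasions = as.integer(n_occasions),
    class = c("mlvi_panel", class(tibble()))
  )
}

#' Build an MLVI panel from trough records
#'
#' Converts raw tacrolimus trough records into a patient-by-occasion panel
#' of MLVI values. With yearly cadence, occasion `y` covers the half-open
#' post-transplant year `(transplant + (y-1) years, transplant + y years]`.
#' With quarterly cadence, occasion `q` is anchored at
#' `transplant + 3q months` and covers the prior 12 months,
#' `(anchor - 12 months, anchor]`; a trough may therefore contribute to up
#' to four overlapping quarterly windows. Each cell's MLVI is the sample SD
#' of the troughs in its window and is present only when the window holds
#' at least 3 troughs.
#'
#' @param troughs Tibble with `patient_id`, `date`, `level_ng_ml`.
#' @param patients Tibble with `patient_id`, `transplant_date`; every
#'   trough's patient must appear here.
#' @param cadence `"yearly"` (default, what the growth mixture model
#'   consumes) or `"quarterly"` (monitoring output).
#' @param n_occasions Number of occasions to cover (years, or quarters).
#' @param divisor Passed to [mlvi_window()].
#' @return A tibble of class `"mlvi_panel"` with columns `patient_id`,
#'   `occasion` (1-based), `mlvi`, `n_troughs`, one row per observed cell.
#'   Attributes: `patient_ids` (all panel patients, observed or not),
#'   `cadence`, `n_occasions`.
#' @export
mlvi_panel <- function(troughs, patients,
                       cadence = c("yearly", "quarterly"),
                       n_occasions = if (cadence == "yearly") 10L else 40L,
                       divisor = c("n-1", "n")) {
  cadence <- match.arg(cadence)
  divisor <- match.arg(divisor)
  force(n_occasions)
  patients <- distinct(patients, .data$patient_id, .data$transplant_date)
  if (nrow(troughs) > 0) {
    unknown <- setdiff(troughs$patient_id, patients$patient_id)
    if (length(unknown) > 0) {
      abort(sprintf("Troughs reference unknown patient id(s): %s",
                    paste(head(unknown, 5), collapse = ", ")),
            class = "adheretraj_data_error")
    }
    bad <- troughs$level_ng_ml <= 0 | !is.finite(troughs$level_ng_ml)
    if (any(bad)) {
      r <- which(bad)[1]
      abort(sprintf(
        "Non-positive trough level for patient '%s' on %s (%s ng/mL).",
        troughs$patient_id[r], format(troughs$date[r]),
        format(troughs$level_ng_ml[r])), class = "adheretraj_data_error")
    }
  }
  tr <- left_join(troughs, patients, by = "patient_id")
  cells <- purrr::map_dfr(seq_len(n_occasions), function(occ) {
    if (cadence == "yearly") {
      lo <- tr$transplant_date %m+% lubridate::years(occ - 1)
      hi <- tr$transplant_date %m+% lubridate::years(occ)
    } else {
      hi <- tr$transplant_date %m+% months(3L * occ)
      lo <- hi %m-% months(12L)
    }
    inside <- tr$date > lo & tr$date <= hi
    if (!any(inside)) return(NULL)
    tr[inside, ] %>%
      group_by(.data$patient_id) %>%
      summarise(mlvi = if (dplyr::n() >= 3) sd(.data$level_ng_ml) else
                  NA_real_,
                n_troughs = dplyr::n(), .groups = "drop") %>%
      mutate(occasion = occ)
  })
  if (nrow(cells) == 0) {
    cells <- tibble(patient_id = character(), occasion = integer(),
                    mlvi = double(), n_troughs = integer())
  } else {
    cells <- cells %>%
      filter(!is.na(.data$mlvi)) %>%
      select("patient_id", "occasion", "mlvi", "n_troughs") %>%
      arrange(.data$patient_id, .data$occasion)
    if (divisor == "n") {
      cells <- mutate(cells, mlvi = .data$mlvi *
                        sqrt((.data$n_troughs - 1) / .data$n_troughs))
    }
  }
  new_mlvi_panel(cells, sort(unique(patients$patient_id)), cadence,
                 n_occasions)
}

#' @export
print.mlvi_panel <- function(x, ...) {
  cat(sprintf("MLVI panel: %d patients, %d %s occasions, %d observed cells\n",
              length(attr(x, "patient_ids")), attr(x, "n_occasions"),
              attr(x, "cadence"), nrow(x)))
  NextMethod()
}

#' Turn an MLVI panel into a value matrix and observation mask
#'
#' @param panel An [mlvi_panel()].
#' @return List with `y` (patients x occasions matrix, `NA` where
#'   unobserved) and `mask` (logical matrix). Row names are patient ids.
#' @export
as_mlvi_matrix <- function(panel) {
  ids <- attr(panel, "patient_ids")
  T_ <- attr(panel, "n_occasions")
  y <- matrix(NA_real_, length(ids), T_,
              dimnames = list(ids, paste0("occ", seq_len(T_))))
  y[cbind(match(panel$patient_id, ids), panel$occasion)] <- panel$mlvi
  list(y = y, mask = !is.na(y))
}

#' Apply cohort eligibility rules
#'
#' Removes repeat-transplant registry rows (only the earliest transplant per
#' patient is analysed) and patients whose last trough falls before 6 months
#' post-transplant (insufficient follow-up); patients with no troughs at all
#' are excluded for the same reason.
#'
#' @param patients Registry tibble with `patient_id`, `transplant_date`
#'   (possibly several rows per patient for repeat transplants).
#' @param troughs Trough tibble with `patient_id`, `date`.
#' @return List with `patients` (retained registry rows) and `exclusions`, a
#'   tally tibble with one row per exclusion reason.
#' @export
eligibility_filter <- function(patients, troughs) {
  first_tx <- patients %>%
    group_by(.data$patient_id) %>%
    arrange(.data$transplant_date, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  n_repeat <- nrow(patients) - nrow(first_tx)

  last_trough <- troughs %>%
    group_by(.data$patient_id) %>%
    summarise(last_date = max(.data$date), .groups = "drop")
  joined <- left_join(first_tx, last_trough, by = "patient_id") %>%
    mutate(ok = !is.na(.data$last_date) &
             .data$last_date >= .data$transplant_date %m+% months(6L))
  retained <- joined %>% filter(.data$ok) %>% select(-"last_date", -"ok")
  list(
    patients = retained,
    exclusions = tibble(
      reason = c("repeat transplant", "follow-up < 6 mo"),
      n = c(n_repeat, sum(!joined$ok))
    )
  )
}

panel_years <- function(panel) {
  per_quarter <- if (attr(panel, "cadence") == "yearly") 1L else 4L
  as.integer(ceiling(panel$occasion / per_quarter))
}

#' Require a minimum number of observed MLVI years
#'
#' Retains patients with at least `min_years` distinct post-transplant years
#' holding an observed MLVI cell (for quarterly panels a year counts once
#' however many of its quarters are observed).
#'
#' @param panel An [mlvi_panel()].
#' @param min_years Minimum distinct years with data (>= 1).
#' @return The filtered panel (same class and attributes; `patient_ids`
#'   restricted to the retained patients).
#' @export
minimum_years_filter <- function(panel, min_years = 4L) {
  stopifnot(min_years >= 1)
  yrs <- panel_years(panel)
  keep <- tibble(patient_id = panel$patient_id, year = yrs) %>%
    distinct() %>%
    count(.data$patient_id) %>%
    filter(.data$n >= min_years) %>%
    pull("patient_id")
  out <- panel[panel$patient_id %in% keep, ]
  new_mlvi_panel(out, intersect(attr(panel, "patient_ids"), keep),
                 attr(panel, "cadence"), attr(panel, "n_occasions"))
}

#' Per-year missingness profile of a yearly panel
#'
#' @param panel A yearly-cadence [mlvi_panel()].
#' @return Tibble with `year`, `n_observed`, `n_patients`, `missing_frac`
#'   (= 1 - observed/patients), one row per panel year.
#' @export
missingness_profile <- function(panel) {
  if (attr(panel, "cadence") != "yearly") {
    abort("`missingness_profile()` expects a yearly-cadence panel.",
          class = "adheretraj_data_error")
  }
  n_pat <- length(attr(panel, "patient_ids"))
  obs <- panel %>% distinct(.data$patient_id, .data$occasion) %>%
    count(.data$occasion)
  tibble(year = seq_len(attr(panel, "n_occasions"))) %>%
    left_join(obs, by = c(year = "occasion")) %>%
    mutate(n_observed = dplyr::coalesce(.data$n, 0L),
           n_patients = n_pat,
           missing_frac = 1 - .data$n_observed / n_pat) %>%
    select("year", "n_observed", "n_patients", "missing_frac")
}
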