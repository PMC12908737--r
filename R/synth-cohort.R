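#' Generate a synthetic transplant cohort
#'
#' Draws a cohort from a two-level generative model: each patient gets a
#' latent adherence class `z ~ Categorical(pi)`, growth factors
#' `(b0, b1) ~ Normal(mu_z, Psi)`, and a latent yearly MLVI
#' `b0 + b1 * (year - 1) + eps_y` with `eps_y ~ Normal(0, theta_y)`,
#' floored at 0.05 so SDs stay positive. For every retained patient-year
#' (years are deleted completely at random per the attrition profile) the
#' generator emits tacrolimus trough records inside that post-transplant
#' year whose sample SD equals the latent MLVI exactly (deterministic mode),
#' so feeding the troughs to [mlvi_panel()] recovers the latent values to
#' machine precision. LAR hospitalization indicators are drawn per retained
#' person-year with class-specific probabilities, and demographics per the
#' configured class-conditional margins.
#'
#' @param config A [synth_config()] object.
#'
#' @return A list of class `"synth_cohort"` with tibbles:
#' \describe{
#'   \item{patients}{`patient_id`, `transplant_date`, `organ`, `sex`,
#'     `race`, `ethnicity`, `insurance`, `life_support`,
#'     `functional_status`.}
#'   \item{troughs}{`patient_id`, `date`, `level_ng_ml` — one row per
#'     tacrolimus assay.}
#'   \item{outcomes}{`patient_id`, `post_tx_year`, `lar_hosp` for every
#'     retained person-year.}
#'   \item{truth}{`patient_id`, `class`, `b0`, `b1` plus the latent yearly
#'     MLVI matrix in `attr(, "latent_mlvi")` and retention mask in
#'     `attr(, "retained")` — ground truth for recovery tests.}
#' }
#' @examples
#' cohort <- synth_cohort(synth_config(n_patients = 20, seed = 1))
#' dplyr::count(cohort$truth, class)
#' @export
synth_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, synth_cohort_impl(config))
}

synth_cohort_impl <- function(config) {
  n <- config$n_patients
  K <- length(config$class_proportions)
  T_ <- config$n_years

  z <- sample.int(K, n, replace = TRUE, prob = config$class_proportions)
  if (length(unique(z)) < K) {
    warn("Some latent classes received zero patients at this sample size.")
  }
  dev <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = config$growth_cov)
  dev <- matrix(dev, ncol = 2)
  b0 <- config$class_growth_means[z, 1] + dev[, 1]
  b1 <- config$class_growth_means[z, 2] + dev[, 2]

  ids <- sprintf("P%04d", seq_len(n))
  tx_date <- as.Date("2009-01-01") +
    sample.int(as.integer(as.Date("2017-12-31") - as.Date("2009-01-01")) + 1L,
               n, replace = TRUE) - 1L

  # latent yearly MLVI, floored at 0.05
  eps <- matrix(rnorm(n * T_, sd = rep(config$resid_sd_by_year, each = n)),
                nrow = n)
  years0 <- matrix(rep(0:(T_ - 1), each = n), nrow = n)
  latent <- pmax(b0 + b1 * years0 + eps, 0.05)
  dimnames(latent) <- list(ids, paste0("year", seq_len(T_)))

  retained <- matrix(runif(n * T_) >=
                       rep(config$attrition_profile, each = n), nrow = n)
  dimnames(retained) <- dimnames(latent)

  # trough records per retained patient-year (vectorised over cells)
  cells <- which(retained, arr.ind = TRUE)
  lat <- latent[cells]
  starts <- tx_date[cells[, 1]] %m+% lubridate::years(cells[, 2] - 1)
  if (config$trough_mode == "deterministic") {
    m <- max(3L, as.integer(round(4 * config$troughs_per_quarter)))
    base <- seq_len(m) - (m + 1) / 2
    base <- base / sd(base)
    counts <- rep(m, nrow(cells))
    # per cell: center + base * latent, the exact-SD ramp of
    # trough_window_construct()
    levels <- rep(config$trough_center, m * nrow(cells)) +
      as.vector(outer(base, lat))
  } else {
    counts <- pmax(3L, rpois(nrow(cells), 4 * config$troughs_per_quarter))
    levels <- pmax(rnorm(sum(counts), config$trough_center,
                         rep(lat, counts)), 0.1)
  }
  offs <- unlist(lapply(counts, function(k) round(seq(15, 350,
                                                      length.out = k))),
                 use.names = FALSE)
  troughs <- tibble(
    patient_id = rep(ids[cells[, 1]], counts),
    date = rep(starts, counts) + offs,
    level_ng_ml = levels
  ) %>% arrange(.data$patient_id, .data$date)

  # outcomes for retained person-years
  outcomes <- tibble(
    patient_id = ids[cells[, 1]],
    post_tx_year = as.integer(cells[, 2]),
    lar_hosp = rbinom(nrow(cells), 1, config$lar_prob_by_class[z[cells[, 1]]])
  ) %>% arrange(.data$patient_id, .data$post_tx_year)

  dm <- config$demographic_margins
  organ_lv <- colnames(dm$organ)
  patients <- tibble(
    patient_id = ids,
    transplant_date = tx_date,
    organ = purrr::map_chr(z, ~ sample(organ_lv, 1, prob = dm$organ[.x, ])),
    sex = if_else(runif(n) < dm$sex_female[z], "female", "male"),
    race = if_else(runif(n) < dm$race_white[z], "White", "Other"),
    ethnicity = if_else(runif(n) < dm$ethnicity_latino[z], "Latino",
                        "Not Latino"),
    insurance = if_else(runif(n) < dm$insurance_public[z], "public",
                        "private"),
    life_support = as.integer(runif(n) < dm$life_support[z]),
    functional_status = rnorm(n, dm$functional_status_mean[z],
                              dm$functional_status_sd[z])
  )

  truth <- tibble(patient_id = ids, class = z, b0 = b0, b1 = b1)
  attr(truth, "latent_mlvi") <- latent
  attr(truth, "retained") <- retained

  structure(
    list(patients = patients, troughs = troughs, outcomes = outcomes,
         truth = truth, config = config),
    class = "synth_cohort"
  )
}

#' Construct trough values with an exact sample SD
#'
#' Deterministically builds `n_troughs` tacrolimus levels whose sample
#' standard deviation (divisor n-1) equals `target_sd` and whose mean equals
#' `center`, by rescaling a centred ramp. Used by the cohort generator so
#' that the simulated troughs are an exact inverse of the MLVI statistic.
#'
#' @param target_sd Desired sample SD, MLVI units (>= 0).
#' @param n_troughs Number of values (>= 3; fewer would be discarded by the
#'   MLVI window rule downstream).
#' @param center Desired mean level, ng/mL.
#' @return Numeric vector of `n_troughs` levels.
#' @examples
#' x <- trough_window_construct(2, 3, 8)
#' sd(x)   # exactly 2
#' mean(x) # exactly 8
#' @export
trough_window_construct <- function(target_sd, n_troughs, center = 8) {
  if (n_troughs < 3) {
    abort("`n_troughs` must be at least 3: smaller windows carry no MLVI.",
          class = "adheretraj_config_error")
  }
  if (target_sd < 0) {
    abort("`target_sd` must be non-negative.",
          class = "adheretraj_config_error")
  }
  if (target_sd == 0) return(rep(center, n_troughs))
  base <- seq_len(n_troughs) - (n_troughs + 1) / 2
  center + base * (target_sd / sd(base))
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("Synthetic transplant cohort\n")
  cat("  patients:", nrow(x$patients), "  troughs:", nrow(x$troughs),
      "  person-years:", nrow(x$outcomes), "\n")
  cat("  classes:", paste(table(x$truth$class), collapse = " / "),
      "  seed:", x$config$seed, "\n")
  invisible(x)
}
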