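#' Configuration for the synthetic transplant cohort generator
#'
#' Bundles and validates every knob of [synth_cohort()]. The defaults emulate
#' the statistical structure of a single-center pediatric transplant cohort:
#' two latent adherence classes in proportions 167:14, class-specific linear
#' MLVI growth with patient-mean MLVI cleanly separated between classes
#' (roughly 1.1--2.1 vs 2.7--4.0 SD units of ng/mL), quarterly trough
#' sampling, yearly missingness rising from about 2.6% in post-transplant
#' year 1 to about 88% in year 10, and per-person-year late-acute-rejection
#' (LAR) hospitalization probabilities of 5.33% vs 7.69% by class.
#'
#' @param n_patients Number of patients to generate.
#' @param class_proportions Probability vector over latent classes; must sum
#'   to 1 and be strictly positive.
#' @param class_growth_means Matrix with one row per class and columns
#'   `(intercept, slope)`: class-mean MLVI at post-transplant year 1 (MLVI
#'   units, i.e. SD of ng/mL) and its mean yearly change (MLVI units/year).
#' @param growth_cov 2x2 covariance of patient-level deviations of
#'   (intercept, slope) from their class means; symmetric positive
#'   semidefinite, shared across classes.
#' @param resid_sd_by_year Per-occasion residual SD of the latent yearly MLVI
#'   around the patient's line; length gives the number of follow-up years.
#' @param troughs_per_quarter Mean trough count per quarter; yearly windows
#'   receive `max(3, round(4 * troughs_per_quarter))` troughs in
#'   deterministic mode.
#' @param attrition_profile Per-year probability that a patient-year yields
#'   no valid MLVI; entries in \[0, 1\], non-decreasing across years.
#' @param lar_prob_by_class Per-person-year LAR hospitalization probability,
#'   one entry per class.
#' @param demographic_margins List of class-conditional margins:
#'   `insurance_public`, `sex_female`, `race_white`, `ethnicity_latino`,
#'   `life_support` (probability per class), `organ` (class x
#'   liver/kidney/heart probability matrix), `functional_status_mean` and
#'   `functional_status_sd` (per class).
#' @param trough_mode `"deterministic"` constructs troughs whose within-year
#'   sample SD equals the latent MLVI exactly (the generator then doubles as
#'   an oracle for the MLVI engine); `"noisy"` samples troughs
#'   `Normal(center, latent MLVI)` for realism.
#' @param trough_center Mean tacrolimus level around which troughs are
#'   placed, ng/mL.
#' @param seed Integer seed; identical configurations produce byte-identical
#'   cohorts.
#'
#' @return A validated list of class `"synth_config"`.
#' @seealso [synth_cohort()]
#' @export
synth_config <- function(n_patients = 181,
                         class_proportions = c(167, 14) / 181,
                         class_growth_means = matrix(
                           c(1.5, 0, 3.3, 0), nrow = 2, byrow = TRUE,
                           dimnames = list(NULL, c("intercept", "slope"))
                         ),
                         growth_cov = diag(c(0.25^2, 0.03^2)),
                         resid_sd_by_year = rep(0.15, 10),
                         troughs_per_quarter = 2.5,
                         attrition_profile = default_attrition_profile(
                           length(resid_sd_by_year)
                         ),
                         lar_prob_by_class = c(0.0533, 0.0769),
                         demographic_margins = default_demographic_margins(),
                         trough_mode = c("deterministic", "noisy"),
                         trough_center = 8,
                         seed = 20090101L) {
  trough_mode <- match.arg(trough_mode)
  K <- length(class_proportions)
  if (abs(sum(class_proportions) - 1) > 1e-12 || any(class_proportions <= 0)) {
    abort("`class_proportions` must be strictly positive and sum to 1.",
          class = "adheretraj_config_error")
  }
  if (!is.matrix(class_growth_means) || nrow(class_growth_means) != K ||
      ncol(class_growth_means) != 2) {
    abort("`class_growth_means` must be a K x 2 (intercept, slope) matrix.",
          class = "adheretraj_config_error")
  }
  if (!isSymmetric(unname(growth_cov)) ||
      min(eigen(growth_cov, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-10) {
    abort("`growth_cov` must be symmetric positive semidefinite.",
          class = "adheretraj_config_error")
  }
  if (any(resid_sd_by_year <= 0)) {
    abort("`resid_sd_by_year` must be strictly positive.",
          class = "adheretraj_config_error")
  }
  n_years <- length(resid_sd_by_year)
  if (length(attrition_profile) != n_years ||
      any(attrition_profile < 0 | attrition_profile > 1) ||
      is.unsorted(attrition_profile)) {
    abort(paste0("`attrition_profile` must have one entry per year, lie in ",
                 "[0, 1], and be non-decreasing."),
          class = "adheretraj_config_error")
  }
  if (length(lar_prob_by_class) != K ||
      any(lar_prob_by_class < 0 | lar_prob_by_class > 1)) {
    abort("`lar_prob_by_class` needs one probability per class.",
          class = "adheretraj_config_error")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      class_proportions = class_proportions,
      class_growth_means = class_growth_means,
      growth_cov = growth_cov,
      resid_sd_by_year = resid_sd_by_year,
      n_years = n_years,
      troughs_per_quarter = troughs_per_quarter,
      attrition_profile = attrition_profile,
      lar_prob_by_class = lar_prob_by_class,
      demographic_margins = demographic_margins,
      trough_mode = trough_mode,
      trough_center = trough_center,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Default yearly missingness profile
#'
#' Logit-linear interpolation between 2.57% missing in post-transplant year 1
#' and 87.71% in year 10, the attrition pattern typical of long-term
#' single-center follow-up.
#'
#' @param n_years Number of follow-up years.
#' @return Numeric vector of per-year missingness probabilities.
#' @export
default_attrition_profile <- function(n_years = 10) {
  plogis(seq(qlogis(0.0257), qlogis(0.8771), length.out = n_years))
}

#' Default class-conditional demographic margins
#'
#' Class-conditional prevalences for insurance, sex, race, ethnicity,
#' pre-transplant life support and organ type, plus functional-status
#' means/SDs, for a two-class (adherent, nonadherent) cohort. Variables are
#' drawn independently given class.
#'
#' @return Named list of margins consumed by [synth_config()].
#' @export
default_demographic_margins <- function() {
  organ <- rbind(
    c(liver = 0.1024, kidney = 0.4790, heart = 0.4157),
    c(liver = 0.2857, kidney = 0.1250, heart = 0.5714)
  )
  organ <- organ / rowSums(organ)
  list(
    insurance_public = c(0.2814, 0.7143),
    sex_female = c(0.5030, 0.2857),
    race_white = c(0.7126, 0.7857),
    ethnicity_latino = c(0.4551, 0.3571),
    life_support = c(0.8263, 0.5714),
    organ = organ,
    functional_status_mean = c(9.56, 9.44),
    functional_status_sd = c(1.27, 2.05)
  )
}
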