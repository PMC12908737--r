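---
title: "Modeling adherence trajectories from tacrolimus trough levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling adherence trajectories from tacrolimus trough levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nonadherence to immunosuppressive medication is among the strongest
predictors of late acute rejection (LAR), hospitalization, and graft loss
after pediatric organ transplantation. Direct observation of pill-taking is
impractical over years of follow-up, but every routine clinic visit yields
a tacrolimus trough level. The **medication level variability index
(MLVI)** exploits this: it is the standard deviation of a patient's trough
levels over a window. A patient who takes tacrolimus consistently holds a
stable trough; erratic adherence produces swings, and a high MLVI.

`adheretraj` implements the full analysis chain from raw assay records to
latent adherence trajectories: MLVI windowing, growth mixture modeling
(GMM) with class enumeration, and between-class profiling of outcomes and
demographics. A synthetic cohort generator with known ground truth makes
every stage testable without patient data.

## MLVI windowing

An MLVI cell is the sample SD (divisor `n - 1`) of the troughs in its
window, and is reported only when the window holds **at least three**
troughs — with one or two values the SD is undefined or worthless. The
divisor is a configuration switch (`divisor = "n"` gives the population
SD); the sample SD is the default because it is the convention of the MLVI
literature.

Two cadences are supported:

* **Quarterly**: occasion `q` is anchored at `transplant + 3q` months and
  covers the preceding 12 months, `(anchor − 12 mo, anchor]`. Adjacent
  windows overlap by construction — a 12-month look-back at a 3-month
  cadence means a trough can contribute to up to four windows. This is the
  direct reading of "the prior 12 months of values".
* **Yearly**: occasion `y` covers post-transplant year `y`,
  `(transplant + (y−1) yr, transplant + y yr]`; windows are disjoint.

All windows are half-open with the **right endpoint included**, anchored on
the transplant date, and use calendar-month arithmetic (not 91.25-day
quarters); this keeps date handling reproducible across leap years. The
mixture model consumes the **yearly** panel with `T = 10` occasions by
default: the free-parameter accounting of the linear specification
(15/18/21 parameters for 1–3 classes) is consistent with 10 occasions, not
40, and a 40-occasion mixture on a ~180-patient cohort would be severely
over-parameterized. Quarterly panels are produced for monitoring output.

Eligibility follows the cohort rules: only a patient's first transplant is
analysed, patients whose last trough falls before 6 months post-transplant
are excluded (tallied per reason), and the analysis panel retains patients
with at least `min_years = 4` distinct observed MLVI years.

## The growth mixture model

Patient `i` in latent class `z_i = k` follows

$$y_i = \Lambda \eta_i + \varepsilon_i, \qquad
  \eta_i \mid z_i = k \sim N(\mu_k, \Psi), \qquad
  \varepsilon_{it} \sim N(0, \theta_t),$$

where `Λ` has row `t` equal to `(1, t)` for occasions coded
`t = 0, …, T−1` — so the intercept is status in post-transplant year 1 —
`μ_k` are class-specific growth-factor means (MLVI units and MLVI
units/year), `Ψ` is the growth-factor covariance and `θ_t` are
occasion-specific residual variances. Free parameters:
`Kq + (K−1) + q(q+1)/2 + T` with `q = 2` for linear growth.

Structural choices, and why:

* **`Ψ` and `θ` shared across classes, means class-specific.** This is the
  only variance structure consistent with the 15/18/21 parameter sequence,
  and the parsimonious default for small minority classes (a 14-patient
  class cannot support its own free covariance). The constructor accepts a
  class-varying flag for forward compatibility, but the estimator
  deliberately implements only the shared structure and says so.
* **Polynomial order.** Quadratic and cubic loadings are available
  (`order = 2, 3`) but documented as fragile: on short panels they
  routinely fail to converge or produce non-positive-definite class
  covariances, which is why the linear form is the default and the one the
  enumeration machinery is tuned for.
* **Missing occasions.** The marginal likelihood evaluates each patient's
  multivariate-normal density on their observed occasions only. This is the
  observed-data likelihood, unbiased when missingness is completely at
  random (MCAR) — the estimator's contract. Attrition correlated with
  adherence itself (a plausible mechanism in real clinics) violates it;
  see Limitations.

## Estimation

EM, with the E-step computing responsibilities in log-space
(log-sum-exp), and closed-form M-step updates using per-pattern
factorisations of the observed-occasion covariance (patients sharing a
missingness pattern share one Cholesky per iteration; the inner loop is
compiled). The observed-data log-likelihood is non-decreasing across
iterations and the suite asserts it.

* **Starts.** Initial values are perturbed k-means-style splits of
  per-patient OLS growth estimates (start 1 is a deterministic
  intercept-rank split). `n_starts` initializations run to a loose relative
  tolerance of `1e-6` (at most 100 iterations); the best `n_final` continue
  to `1e-8`. Package defaults are 200/50; desk-scale analyses in the tests
  use 8–16/2–4, which is ample under strong separation. The starts report
  records every final log-likelihood and whether the best value replicated
  (≥ 2 final solutions within `1e-4`) — an unreplicated maximum is a
  warning sign of an under-explored likelihood surface.
* **Iteration cap.** EM on this model partitions variance between `Ψ` and
  `θ` and converges linearly but slowly when occasions are nearly
  deterministic; on the default synthetic panel the one-class fit needs
  about 3,200 iterations to meet `1e-8`. The final-stage cap is therefore
  5,000 iterations.
* **Degeneracy is flagged, not masked.** Floors — `θ_t ≥ 1e-6`, `Ψ`
  projected onto the PSD cone, `π_k ≥ 1/(10n)` — exist to keep arithmetic
  finite, and *hitting any of them marks the fit not converged* with a
  named flag (`residual-variance-floor`,
  `nonpositive-definite-growth-covariance`, `empty-class`) and a warning.
  If no start converges at all, the fit errors with diagnostics.
* **Label canonicalization.** Classes are sorted by intercept mean
  ascending (ties by slope), so class 1 is always the low-MLVI, adherent
  trajectory and repeated runs are comparable.
* **No robust standard errors.** Point estimation and likelihood only;
  sandwich SEs are out of scope.

## Class enumeration

`enumerate_classes()` fits `K = 1..k_max` and tabulates free parameters,
AIC (`2p − 2LL`), BIC (`p ln n − 2LL`, `n` = patients, natural log),
entropy, and likelihood-ratio tests. Entropy is
`1 − Σᵢₖ(−p̂ᵢₖ ln p̂ᵢₖ)/(n ln K)`: 1 for one-hot posteriors, 0 for
uninformative ones, with 0.8 the conventional "well separated" bar.

Two LRTs compare `K` against `K−1`:

* **Adjusted LRT (VLMR/LMR-style).** `2ΔLL` divided by the small-sample
  correction `1 + 1/(d ln n)` and referred to a χ²(d) distribution, `d`
  the parameter-count difference. The true null distribution of a mixture
  LRT is a weighted χ² mixture, not χ²(d), so this p-value is an
  **approximation and advisory only** — it is reported, never decisive,
  and its null calibration is not asserted in the test suite.
* **Bootstrap LRT (reference).** Parametric bootstrap under the `K−1`
  fit: simulate panels from the null parameters with the observed
  missingness mask, refit both models with identical (small) start
  settings and a looser `1e-6` final tolerance — over-specified mixtures
  approach their optimum along a flat ridge, and what matters is that
  observed and null statistics are computed under the same regime — and
  report `p = (1 + #[stat_b ≥ stat_obs])/(B + 1)`. Non-convergent
  replicates are redrawn and counted. Its null uniformity *is* asserted in
  the suite.

**Recommendation rule** (each verdict echoed in the output): among
converged candidates, any `K > 1` must have entropy ≥ 0.8 to be eligible;
the smallest `K` attaining the minimum BIC wins. The LRT is deliberately
advisory: with a small, extremely well-separated minority class, BIC and
entropy can clearly favour `K = 2` while the adjusted LRT is equivocal,
and the rule codifies retaining the BIC/entropy choice while printing the
LRT caveat.

## Class profiling

* **Separation** is assessed on **patient-mean MLVI over observed
  occasions** — the longitudinal average, not single windows. When the
  two-class ranges are disjoint the report gives the gap interval and its
  midpoint as a descriptive threshold; it is a property of this sample and
  should not be read as a universal diagnostic cut-point.
* **Fisher exact** rows use the conditional-MLE odds ratio with the exact
  test-inversion CI (the `stats::fisher.test` convention), oriented
  class 1 vs class 2.
* **Mann-Whitney U** is `#[a > b] + ½#[a = b]`, reported as
  `min(U_a, U_b)` so fully disjoint samples print `U = 0`; p-values are
  exact for tie-free totals ≤ 25, otherwise normal approximation with tie
  and continuity correction.
* **Cliff's delta** is positive when class-1 values tend larger; the sign
  convention is stated because it is not recoverable from group summaries
  alone. The CI uses Cliff's consistent variance estimate with the
  asymmetric variance-stabilized interval.
* **LAR rates** are reported both per patient (any event across follow-up)
  and per person-year, over *observed* person-years.

No multiplicity correction is applied across comparison rows, matching the
descriptive intent of the table.

## The synthetic cohort generator

`synth_config()` defaults emulate a single-center pediatric cohort of 181
heart/liver/kidney recipients:

* two latent classes in proportions 167:14, with linear growth means
  (1.5, 0) and (3.3, 0) MLVI units, shared growth-factor covariance
  `diag(0.25², 0.03²)` and yearly residual SD 0.15 — chosen so patient-mean
  MLVI ranges are completely disjoint between classes (roughly 1.1–2.1 vs
  2.7–4.0) in ≈99% of seeds at n = 181;
* yearly MCAR attrition interpolated logit-linearly from 2.57% missing in
  year 1 to 87.71% in year 10 (each patient-year deleted independently —
  consistent with the estimator's MCAR contract, deliberately not an
  informative mechanism);
* per-person-year LAR probabilities 5.33% vs 7.69% by class;
* demographics drawn independently given class from class-conditional
  margins (public insurance ≈28% vs ≈71%, female ≈50% vs ≈29%, life
  support ≈83% vs ≈57%, organ mix, functional status 9.56 ± 1.27 vs
  9.44 ± 2.05). No between-covariate correlation is induced because only
  class-conditional margins are specified.

The latent yearly MLVI is floored at 0.05 (an SD cannot be negative; the
floor keeps degenerate draws positive). In **deterministic mode** the
generator emits, for every retained patient-year, troughs constructed by
rescaling a centred ramp so their sample SD equals the latent MLVI and
their mean equals 8 ng/mL *exactly*; feeding them back through
`mlvi_panel()` reproduces the latent matrix to machine precision, making
the generator an oracle for the windowing code. A **noisy mode** samples
troughs `Normal(8, MLVI)` for more realistic level traces.

One documented inconsistency in the emulation target: published per-class
MLVI summaries of the form mean ± SD (1.46 ± 1.51 / 3.75 ± 2.77) cannot
coexist with patient-mean ranges 1.07–2.10 / 2.67–3.99 unless the SDs are
observation-level. The generator calibrates to the **ranges** and treats
the mean ± SD pairs as observation-level summaries; it does not attempt to
match both.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: tacrolimus pharmacokinetics and
dose-level dynamics, assay-method differences, informative missingness
(sicker or less adherent patients dropping out), correlated demographics,
and measurement error in transplant or assay dates.

## Numerical choices at a glance

| Quantity | Value | Why |
|---|---|---|
| Loose / final EM tolerance | `1e-6` / `1e-8` relative | two-stage starts regime |
| Bootstrap-refit tolerance | `1e-6` | flat ridge under the null; symmetric treatment |
| Final iteration cap | 5,000 | slow linear EM convergence measured at desk scale |
| `θ` floor / `π` floor | `1e-6` / `1/(10n)` | detect (and flag) degeneracy, not mask it |
| Replication window | `1e-4` on final LL | "same maximum" across starts |
| Modal-assignment tie | lower class index | deterministic output |
| Entropy bar for K > 1 | 0.8 | conventional separation threshold |
| Latent MLVI floor | 0.05 | SDs must stay positive |

Desk-scale problem sizes used by the test suite, chosen to exercise the
study design while keeping a full run on one CPU comfortable: recovery and
enumeration across 50 simulated 181-patient cohorts (12/3 starts);
bootstrap-LRT calibration with 50 outer replicates of a 60-patient,
5-occasion null at `B = 99`; oracle sweeps over every 2×2 table with total
≤ 24 and random small mixture instances.

## Limitations

* The MCAR assumption is untestable from the panel alone; with attrition
  approaching 88% by year 10, informative dropout would bias late-year
  trajectory estimates.
* The adjusted (VLMR-style) LRT p-value is approximate; use the bootstrap
  LRT when the decision matters.
* Class-varying covariance structures and covariate-conditioned mixtures
  (predictors of class membership or growth) are not implemented; the
  latter are known to destabilize estimation on cohorts of this size.
* The separation threshold is descriptive. With a 14-patient minority
  class, its location is sensitive to single patients; multicenter
  validation would be needed before any clinical use.
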