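#' Modal classification and average posterior probabilities
#'
#' Assigns each patient to the class with the highest posterior probability
#' (ties broken toward the lower class index) and computes the AvePP
#' matrix: entry (j, k) is the mean posterior probability of class k among
#' patients modally assigned to class j. A diagonal near 1 indicates
#' reliable assignment.
#'
#' @param responsibilities n x K posterior matrix (rows sum to 1) with
#'   patient ids as row names, or a [fit_gmm()] object.
#' @return Object of class `"classification_summary"`: `assignment` tibble
#'   (`patient_id`, `class`, `posterior`), `counts` (per-class n), `avepp`
#'   (K x K matrix).
#' @export
classify <- function(responsibilities) {
  if (inherits(responsibilities, "gmm_fit")) {
    responsibilities <- responsibilities$responsibilities
  }
  p <- as.matrix(responsibilities)
  K <- ncol(p)
  cls <- max.col(p, ties.method = "first")
  avepp <- t(sapply(seq_len(K), function(j) {
    idx <- which(cls == j)
    if (length(idx) == 0) rep(NA_real_, K)
    else colMeans(p[idx, , drop = FALSE])
  }))
  avepp <- matrix(avepp, nrow = K,
                  dimnames = list(paste0("assigned_", seq_len(K)),
                                  paste0("class_", seq_len(K))))
  structure(
    list(
      assignment = tibble(
        patient_id = rownames(p) %||% as.character(seq_len(nrow(p))),
        class = cls,
        posterior = p[cbind(seq_len(nrow(p)), cls)]
      ),
      counts = tabulate(cls, K),
      avepp = avepp
    ),
    class = "classification_summary"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.classification_summary <- function(x, ...) {
  cat("Modal classification:", paste(x$counts, collapse = " / "),
      "patients per class\n")
  cat("AvePP (rows = assigned class):\n")
  print(round(x$avepp, 3))
  invisible(x)
}

#' Separation of patient-mean MLVI between classes
#'
#' Computes each patient's mean MLVI over observed occasions, the per-class
#' range of those means, and whether the class ranges overlap. When the
#' two-class ranges are disjoint, the gap interval (max of the lower class,
#' min of the upper class) and its midpoint are reported as a descriptive
#' classification threshold. The midpoint is a data-driven summary of this
#' sample, not a universal diagnostic cut-point.
#'
#' @param panel An [mlvi_panel()].
#' @param labels Tibble with `patient_id` and `class`, or a
#'   `classification_summary`.
#' @return Object of class `"separation_report"`: `ranges` tibble (class,
#'   n, min, max of patient-mean MLVI), `overlap` flag, and for disjoint
#'   two-class solutions `gap_lower`, `gap_upper`, `threshold` (midpoint).
#' @export
separation_analysis <- function(panel, labels) {
  if (inherits(labels, "classification_summary")) labels <- labels$assignment
  pm <- panel %>%
    group_by(.data$patient_id) %>%
    summarise(mean_mlvi = mean(.data$mlvi), .groups = "drop") %>%
    left_join(select(labels, "patient_id", "class"), by = "patient_id")
  if (any(is.na(pm$class))) {
    abort("Every panel patient needs a class label.",
          class = "adheretraj_data_error")
  }
  ranges <- pm %>%
    group_by(.data$class) %>%
    summarise(n = dplyr::n(), min = min(.data$mean_mlvi),
              max = max(.data$mean_mlvi), .groups = "drop") %>%
    arrange(.data$min)
  if (nrow(ranges) < length(unique(labels$class))) {
    abort("A class has zero patients in the panel.",
          class = "adheretraj_data_error")
  }
  overlap <- FALSE
  if (nrow(ranges) > 1) {
    for (i in seq_len(nrow(ranges) - 1)) {
      if (ranges$max[i] >= ranges$min[i + 1]) overlap <- TRUE
    }
  }
  out <- list(ranges = ranges, overlap = overlap, gap_lower = NA_real_,
              gap_upper = NA_real_, threshold = NA_real_)
  if (!overlap && nrow(ranges) == 2) {
    out$gap_lower <- ranges$max[1]
    out$gap_upper <- ranges$min[2]
    out$threshold <- (out$gap_lower + out$gap_upper) / 2
  }
  structure(out, class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("Patient-mean MLVI ranges by class:\n")
  print(as.data.frame(x$ranges), digits = 4, row.names = FALSE)
  if (x$overlap) {
    cat("Class ranges OVERLAP: no separating threshold.\n")
  } else if (!is.na(x$threshold)) {
    cat(sprintf("Disjoint: gap (%.3f, %.3f), midpoint threshold %.3f\n",
                x$gap_lower, x$gap_upper, x$threshold))
  } else {
    cat("Class ranges disjoint.\n")
  }
  invisible(x)
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided exact test on the noncentral hypergeometric distribution: the
#' p-value sums point probabilities no larger than the observed one at
#' OR = 1, the odds ratio is the conditional maximum-likelihood estimate,
#' and the confidence interval inverts the exact test (the convention of
#' [stats::fisher.test()], which performs the computation).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param conf_level Confidence level for the OR interval.
#' @return One-row tibble: `odds_ratio` (conditional MLE), `conf_low`,
#'   `conf_high`, `p_value`.
#' @export
fisher_exact <- function(table, conf_level = 0.95) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2))
  if (any(table < 0) || any(table != round(table))) {
    abort("Counts must be non-negative integers.",
          class = "adheretraj_data_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Fisher exact test undefined: a table margin is zero.",
          class = "adheretraj_data_error")
  }
  ft <- fisher.test(table, conf.level = conf_level)
  tibble(odds_ratio = unname(ft$estimate), conf_low = ft$conf.int[1],
         conf_high = ft$conf.int[2], p_value = ft$p.value)
}

#' Mann-Whitney U test
#'
#' `U_a = #[a > b] + 0.5 #[a = b]` over all pairs; the reported statistic is
#' `min(U_a, U_b)`, so fully disjoint samples give U = 0. The p-value is
#' exact for small tie-free samples (total n <= 25) and otherwise uses the
#' normal approximation with tie correction and continuity correction (via
#' [stats::wilcox.test()]).
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return One-row tibble: `statistic` (min U), `u_a`, `u_b`, `p_value`.
#' @export
mann_whitney <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  na <- length(sample_a); nb <- length(sample_b)
  r <- rank(c(sample_a, sample_b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  p <- suppressWarnings(
    wilcox.test(sample_a, sample_b,
                exact = (na + nb <= 25) && !ties, correct = TRUE)$p.value)
  tibble(statistic = min(u_a, u_b), u_a = u_a, u_b = u_b, p_value = p)
}

#' Cliff's delta effect size
#'
#' `delta = (#[a > b] - #[a < b]) / (n_a n_b)`: the probability that a value
#' from `sample_a` exceeds one from `sample_b`, minus the reverse. Positive
#' values mean `sample_a` tends larger. The confidence interval uses
#' Cliff's consistent variance estimate with the asymmetric
#' variance-stabilized interval. On tie-free data the identity
#' `delta = 1 - 2 U_b / (n_a n_b)` links it to [mann_whitney()].
#'
#' @inheritParams mann_whitney
#' @param conf_level Confidence level.
#' @return One-row tibble: `delta`, `conf_low`, `conf_high`.
#' @export
cliffs_delta <- function(sample_a, sample_b, conf_level = 0.95) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  na <- length(sample_a); nb <- length(sample_b)
  d_ij <- sign(outer(sample_a, sample_b, `-`))
  d <- mean(d_ij)
  di <- rowMeans(d_ij)
  dj <- colMeans(d_ij)
  if (na == 1 || nb == 1) {
    return(tibble(delta = d, conf_low = NA_real_, conf_high = NA_real_))
  }
  s2 <- (nb^2 * sum((di - d)^2) + na^2 * sum((dj - d)^2) -
           sum((d_ij - d)^2)) / (na * nb * (na - 1) * (nb - 1))
  s2 <- max(s2, 0)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (s2 == 0) {
    lo <- hi <- d
  } else {
    den <- 1 - d^2 + z^2 * s2
    rad <- z * sqrt(s2) * sqrt(max((1 - d^2)^2 + z^2 * s2, 0))
    lo <- (d - d^3 - rad) / den
    hi <- (d - d^3 + rad) / den
  }
  tibble(delta = d, conf_low = max(lo, -1), conf_high = min(hi, 1))
}

#' Per-class LAR hospitalization rates
#'
#' All-years rate: percentage of patients with at least one LAR
#' hospitalization across follow-up. Per-person-year rate: LAR person-years
#' as a percentage of observed person-years.
#'
#' @param outcomes Tibble with `patient_id`, `post_tx_year`, `lar_hosp`
#'   (0/1).
#' @param labels Tibble with `patient_id`, `class`, or a
#'   `classification_summary`.
#' @return Tibble with one row per class: `class`, `n_patients`,
#'   `person_years`, `pct_any_lar`, `pct_lar_per_year`.
#' @export
outcome_rates <- function(outcomes, labels) {
  if (inherits(labels, "classification_summary")) labels <- labels$assignment
  labels <- select(labels, "patient_id", "class")
  missing_lab <- setdiff(outcomes$patient_id, labels$patient_id)
  if (length(missing_lab) > 0) {
    abort(sprintf("Outcome rows without a class label: %s",
                  paste(head(missing_lab, 5), collapse = ", ")),
          class = "adheretraj_data_error")
  }
  joined <- left_join(outcomes, labels, by = "patient_id")
  per_patient <- joined %>%
    group_by(.data$class, .data$patient_id) %>%
    summarise(any_lar = as.integer(any(.data$lar_hosp > 0)),
              .groups = "drop")
  pat <- per_patient %>%
    group_by(.data$class) %>%
    summarise(n_patients = dplyr::n(), pct_any_lar = 100 * mean(.data$any_lar),
              .groups = "drop")
  py <- joined %>%
    group_by(.data$class) %>%
    summarise(person_years = dplyr::n(),
              pct_lar_per_year = 100 * mean(.data$lar_hosp > 0),
              .groups = "drop")
  left_join(pat, py, by = "class") %>%
    select("class", "n_patients", "person_years", "pct_any_lar",
           "pct_lar_per_year")
}

binary_row <- function(name, x, cls, positive) {
  lv <- sort(unique(cls))
  tab <- rbind(
    c(sum(x == positive & cls == lv[1]), sum(x != positive & cls == lv[1])),
    c(sum(x == positive & cls == lv[2]), sum(x != positive & cls == lv[2]))
  )
  ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  fe <- if (ok) fisher_exact(tab) else
    tibble(odds_ratio = NA_real_, conf_low = NA_real_,
           conf_high = NA_real_, p_value = NA_real_)
  tibble(
    variable = name,
    class1 = sprintf("%d (%.1f%%)", tab[1, 1], 100 * tab[1, 1] /
                       sum(tab[1, ])),
    class2 = sprintf("%d (%.1f%%)", tab[2, 1], 100 * tab[2, 1] /
                       sum(tab[2, ])),
    test = "Fisher exact", statistic = NA_real_, p_value = fe$p_value,
    effect = "odds ratio", estimate = fe$odds_ratio,
    conf_low = fe$conf_low, conf_high = fe$conf_high
  )
}

continuous_row <- function(name, x, cls) {
  lv <- sort(unique(cls))
  a <- x[cls == lv[1]]; b <- x[cls == lv[2]]
  mw <- mann_whitney(a, b)
  cd <- cliffs_delta(a, b)
  tibble(
    variable = name,
    class1 = sprintf("%.2f ± %.2f", mean(a), sd(a)),
    class2 = sprintf("%.2f ± %.2f", mean(b), sd(b)),
    test = "Mann-Whitney U", statistic = mw$statistic,
    p_value = mw$p_value, effect = "Cliff's delta", estimate = cd$delta,
    conf_low = cd$conf_low, conf_high = cd$conf_high
  )
}

#' Between-class comparison table of demographics and outcomes
#'
#' Builds the per-variable comparison table for a two-class solution:
#' binary variables get a Fisher exact test with conditional-MLE odds ratio
#' and exact CI; continuous variables get a Mann-Whitney U test with
#' Cliff's delta. Class 1 (the low-MLVI, adherent trajectory) is the first
#' column, and odds ratios are oriented class 1 vs class 2.
#'
#' @param patients Registry tibble (columns `insurance`, `sex`, `race`,
#'   `ethnicity`, `life_support`, `functional_status` are used when
#'   present).
#' @param labels Tibble with `patient_id`, `class`, or a
#'   `classification_summary`.
#' @param outcomes Optional outcomes tibble; adds an "any LAR
#'   hospitalization" row.
#' @return Tibble with one row per compared variable.
#' @export
compare_classes <- function(patients, labels, outcomes = NULL) {
  if (inherits(labels, "classification_summary")) labels <- labels$assignment
  df <- left_join(patients, select(labels, "patient_id", "class"),
                  by = "patient_id") %>%
    filter(!is.na(.data$class))
  if (length(unique(df$class)) != 2) {
    abort("`compare_classes()` expects exactly two classes.",
          class = "adheretraj_data_error")
  }
  rows <- list()
  if (!is.null(outcomes)) {
    any_lar <- outcomes %>%
      group_by(.data$patient_id) %>%
      summarise(any_lar = any(.data$lar_hosp > 0), .groups = "drop")
    dfo <- left_join(df, any_lar, by = "patient_id") %>%
      mutate(any_lar = dplyr::coalesce(.data$any_lar, FALSE))
    rows <- c(rows, list(binary_row("LAR hospitalization, any year",
                                    dfo$any_lar, dfo$class, TRUE)))
  }
  spec <- list(
    c("insurance", "Insurance, public", "public"),
    c("sex", "Sex, female", "female"),
    c("race", "Race, White", "White"),
    c("ethnicity", "Ethnicity, Latino", "Latino")
  )
  for (s in spec) {
    if (s[1] %in% names(df)) {
      rows <- c(rows, list(binary_row(s[2], df[[s[1]]], df$class, s[3])))
    }
  }
  if ("life_support" %in% names(df)) {
    rows <- c(rows, list(binary_row("Life support, yes",
                                    df$life_support, df$class, 1L)))
  }
  if ("functional_status" %in% names(df)) {
    rows <- c(rows, list(continuous_row("Functional status",
                                        df$functional_status, df$class)))
  }
  bind_rows(rows)
}
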