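#' Plot observed MLVI trajectories and fitted class means
#'
#' Spaghetti plot of each patient's observed MLVI over occasions, coloured
#' by modal class, with the model-implied class mean trajectories
#' (`Lambda mu_k`) overlaid.
#'
#' @param object A [fit_gmm()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gmm_fit
#' @export
autoplot.gmm_fit <- function(object, ...) {
  cls <- classify(object)
  df <- object$panel %>%
    left_join(cls$assignment, by = "patient_id") %>%
    mutate(class = factor(.data$class))
  means <- purrr::map_dfr(seq_len(object$spec$K), function(k) {
    tibble(occasion = seq_len(object$spec$n_occasions),
           mlvi = as.numeric(object$params$lambda %*%
                               object$params$mu[k, ]),
           class = factor(k))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$occasion, y = .data$mlvi,
                                   colour = .data$class)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = means, linewidth = 1.2) +
    ggplot2::labs(x = "Post-transplant year", y = "MLVI (SD of ng/mL)",
                  colour = "Trajectory",
                  title = "MLVI over time by latent trajectory") +
    ggplot2::theme_minimal()
}

#' Plot class-enumeration fit indices
#'
#' BIC and entropy against the candidate number of classes, with the
#' recommended K marked.
#'
#' @param object A [enumerate_classes()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gmm_enumeration
#' @export
autoplot.gmm_enumeration <- function(object, ...) {
  df <- object$table %>%
    select("K", "bic", "entropy") %>%
    tidyr::pivot_longer(c("bic", "entropy"), names_to = "index") %>%
    mutate(index = dplyr::recode(.data$index, bic = "BIC",
                                 entropy = "Entropy"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$recommended_K,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "Number of classes",
                  title = "Class enumeration fit indices") +
    ggplot2::theme_minimal()
}

#' Plot per-class mean MLVI with standard-error bars
#'
#' Observed per-occasion class means with +/- 1 SE bars, the classic
#' class-profile figure.
#'
#' @param panel An [mlvi_panel()].
#' @param labels Tibble `patient_id`/`class` or a `classification_summary`.
#' @return A ggplot.
#' @export
plot_class_profiles <- function(panel, labels) {
  if (inherits(labels, "classification_summary")) labels <- labels$assignment
  df <- panel %>%
    left_join(select(labels, "patient_id", "class"), by = "patient_id") %>%
    group_by(.data$class, .data$occasion) %>%
    summarise(mean_mlvi = mean(.data$mlvi),
              se = sd(.data$mlvi) / sqrt(dplyr::n()), n = dplyr::n(),
              .groups = "drop") %>%
    mutate(class = factor(.data$class))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$occasion, y = .data$mean_mlvi,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_mlvi - .data$se,
      ymax = .data$mean_mlvi + .data$se)) +
    ggplot2::labs(x = "Post-transplant year", y = "Mean MLVI (+/- SE)",
                  colour = "Trajectory",
                  title = "Class mean MLVI with standard errors") +
    ggplot2::theme_minimal()
}

#' Plot the yearly missingness profile
#'
#' @param profile Output of [missingness_profile()].
#' @return A ggplot.
#' @export
plot_missingness <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$year,
                                        y = .data$missing_frac)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = "Post-transplant year",
                  y = "Patients missing a yearly MLVI",
                  title = "Observation attrition over follow-up") +
    ggplot2::theme_minimal()
}
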