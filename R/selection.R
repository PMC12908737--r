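#' Akaike information criterion
#'
#' `AIC = 2p - 2 loglik`.
#'
#' @param loglik Maximized log-likelihood.
#' @param p Number of free parameters (>= 1).
#' @return The AIC value (lower is better).
#' @export
aic <- function(loglik, p) {
  stopifnot(p >= 1)
  2 * p - 2 * loglik
}

#' Bayesian information criterion
#'
#' `BIC = p ln(n) - 2 loglik` with `n` the number of patients (rows) and
#' natural logarithm.
#'
#' @inheritParams aic
#' @param p Number of free parameters.
#' @param n Number of patients (>= 2).
#' @return The BIC value (lower is better).
#' @export
bic <- function(loglik, p, n) {
  stopifnot(n >= 2)
  p * log(n) - 2 * loglik
}

#' Classification entropy of a mixture model
#'
#' `1 - sum_i sum_k (-p_ik ln p_ik) / (n ln K)`: 1 means perfectly separated
#' classes (one-hot posteriors), 0 means uninformative classification
#' (uniform posteriors). Values of 0.8 or above are conventionally read as
#' well-separated trajectories. Undefined for K = 1.
#'
#' @param responsibilities n x K posterior probability matrix (rows sum to
#'   1), or a [fit_gmm()] object.
#' @return Entropy in \[0, 1\], or `NA` for K = 1.
#' @export
entropy <- function(responsibilities) {
  if (inherits(responsibilities, "gmm_fit")) {
    responsibilities <- responsibilities$responsibilities
  }
  K <- ncol(responsibilities)
  if (K < 2) return(NA_real_)
  p <- responsibilities
  h <- -p * log(p)
  h[p == 0] <- 0
  1 - sum(h) / (nrow(p) * log(K))
}

lrt_stat <- function(fit_k, fit_km1) {
  stat <- 2 * (fit_k$loglik - fit_km1$loglik)
  if (stat < -1e-6) {
    abort(sprintf(
      paste0("Larger model has lower log-likelihood (2*dLL = %.4g): the ",
             "K-class optimizer under-performed; re-fit with more starts."),
      stat), class = "adheretraj_convergence_error")
  }
  max(stat, 0)
}

#' Adjusted likelihood-ratio test for K vs K-1 classes (VLMR/LMR-style)
#'
#' Computes `2(LL_K - LL_{K-1})`, applies a Lo-Mendell-Rubin-style
#' small-sample adjustment (division by `1 + 1/(d ln n)`, `d` the
#' parameter-count difference), and refers the adjusted statistic to a
#' chi-square with `d` degrees of freedom. The chi-square reference is an
#' approximation — the true null distribution of a mixture LRT is a weighted
#' chi-square mixture — so the p-value is advisory; [lrt_bootstrap()] is the
#' reference test.
#'
#' @param fit_k,fit_km1 [fit_gmm()] results on the same panel with K and
#'   K-1 classes.
#' @param n Number of patients; defaults to `fit_k$n`.
#' @return Tibble with `statistic` (raw 2*dLL), `adjusted`, `df`,
#'   `p_value`.
#' @export
lrt_vlmr <- function(fit_k, fit_km1, n = fit_k$n) {
  stat <- lrt_stat(fit_k, fit_km1)
  d <- count_free_parameters(fit_k$spec) -
    count_free_parameters(fit_km1$spec)
  adj <- stat / (1 + 1 / (d * log(n)))
  tibble(statistic = stat, adjusted = adj, df = d,
         p_value = pchisq(adj, df = d, lower.tail = FALSE))
}

#' Parametric bootstrap likelihood-ratio test for K vs K-1 classes
#'
#' Simulates `B` panels from the fitted (K-1)-class model (the null), with
#' the missingness mask copied from the observed panel, refits both models
#' on each, and returns `p = (1 + #[stat_b >= stat_obs]) / (B + 1)`.
#' Replicates on which either null refit fails to converge are redrawn, up
#' to `B` redraws in total; the redraw count is reported.
#'
#' @inheritParams lrt_vlmr
#' @param B Number of bootstrap replicates (>= 19).
#' @param seed Integer seed for the bootstrap draws and refit starts.
#' @param n_starts,n_final Start counts for the bootstrap refits (kept small
#'   by default; the statistic only needs the likelihood ratio, computed
#'   with identical settings under observed and simulated data).
#' @param refit_tol,refit_max_iter Final-stage tolerance and iteration cap
#'   for the bootstrap refits; looser than the headline fit because
#'   over-specified mixtures approach their optimum along a flat ridge. For
#'   a valid comparison the observed-data fits should use comparable
#'   settings.
#' @return List with `p_value`, `stat_obs`, `stats` (the B null statistics),
#'   `B`, `n_redrawn`.
#' @export
lrt_bootstrap <- function(fit_k, fit_km1, B = 99L, seed = 1L,
                          n_starts = 4L, n_final = 1L, refit_tol = 1e-6,
                          refit_max_iter = 4000L) {
  stopifnot(B >= 19)
  stat_obs <- lrt_stat(fit_k, fit_km1)
  panel <- fit_km1$panel
  spec0 <- fit_km1$spec; spec1 <- fit_k$spec
  stats <- numeric(B)
  n_redrawn <- 0L
  b <- 1L; draw <- 0L
  while (b <= B) {
    draw <- draw + 1L
    sim <- simulate_from_model(fit_km1$params, fit_km1$n,
                               missing_mask_source = panel,
                               seed = seed + 7L * draw)
    res <- tryCatch({
      f0 <- fit_gmm(sim, spec0, n_starts = n_starts, n_final = n_final,
                    seed = seed + 7L * draw + 1L, tol_final = refit_tol,
                    max_iter = refit_max_iter, max_iter_loose = 25L)
      f1 <- suppressWarnings(
        fit_gmm(sim, spec1, n_starts = n_starts, n_final = n_final,
                seed = seed + 7L * draw + 2L, tol_final = refit_tol,
                max_iter = refit_max_iter, max_iter_loose = 25L))
      lrt_stat(f1, f0)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > B) {
        abort("Too many non-convergent bootstrap replicates.",
              class = "adheretraj_convergence_error")
      }
      next
    }
    stats[b] <- res
    b <- b + 1L
  }
  list(p_value = (1 + sum(stats >= stat_obs)) / (B + 1),
       stat_obs = stat_obs, stats = stats, B = B, n_redrawn = n_redrawn)
}

#' Enumerate latent trajectory classes
#'
#' Fits the growth mixture model for `K = 1..k_max`, assembles the
#' class-enumeration table (free parameters, AIC, BIC, entropy, adjusted
#' LRT p, optionally bootstrap LRT p), and recommends a class count.
#' Recommendation rule: among converged models — requiring entropy >= 0.8
#' for any K > 1 to be eligible — pick the smallest K attaining the minimum
#' BIC. LRT p-values are reported but advisory (a K can be retained on
#' BIC/entropy grounds even when the LRT cannot reject K-1). Every rule
#' applied is echoed in the `rules` field. Models that fail to converge are
#' flagged and enumeration continues.
#'
#' @param panel An [mlvi_panel()].
#' @param k_max Largest class count to consider (>= 2).
#' @param base_spec A [growth_spec()] whose `K` is overridden per candidate.
#' @param n_starts,n_final,seed Passed to [fit_gmm()].
#' @param blrt_B Bootstrap-LRT replicates per comparison; 0 (default) skips
#'   the bootstrap.
#' @return Object of class `"gmm_enumeration"`: `table` (one row per K),
#'   `fits` (list of `gmm_fit`), `recommended_K`, `rules` (character log of
#'   the decision).
#' @export
enumerate_classes <- function(panel, k_max = 3L,
                              base_spec = growth_spec(1L),
                              n_starts = 200L, n_final = 50L, seed = 1L,
                              blrt_B = 0L) {
  stopifnot(k_max >= 2)
  n <- length(attr(panel, "patient_ids"))
  fits <- vector("list", k_max)
  rows <- vector("list", k_max)
  for (K in seq_len(k_max)) {
    spec <- growth_spec(K, base_spec$n_occasions, base_spec$order,
                        base_spec$variance_structure,
                        base_spec$residual_structure)
    p <- count_free_parameters(spec)
    fit <- tryCatch(
      suppressWarnings(fit_gmm(panel, spec, n_starts = n_starts,
                               n_final = n_final, seed = seed + 100L * K)),
      error = function(e) NULL)
    fits[[K]] <- fit
    if (is.null(fit)) {
      rows[[K]] <- tibble(K = K, free_parameters = p, loglik = NA_real_,
                          aic = NA_real_, bic = NA_real_,
                          entropy = NA_real_, vlmr_p = NA_real_,
                          blrt_p = NA_real_, converged = FALSE,
                          flags = "did-not-converge")
      next
    }
    vl <- if (K > 1 && !is.null(fits[[K - 1]]))
      tryCatch(lrt_vlmr(fit, fits[[K - 1]], n)$p_value,
               error = function(e) NA_real_)
    else NA_real_
    bl <- NA_real_
    if (blrt_B > 0 && K > 1 && !is.null(fits[[K - 1]])) {
      bl <- tryCatch(
        lrt_bootstrap(fit, fits[[K - 1]], B = blrt_B,
                      seed = seed + 17L * K)$p_value,
        error = function(e) NA_real_)
    }
    rows[[K]] <- tibble(
      K = K, free_parameters = p, loglik = fit$loglik,
      aic = aic(fit$loglik, p), bic = bic(fit$loglik, p, fit$n),
      entropy = entropy(fit), vlmr_p = vl, blrt_p = bl,
      converged = fit$converged,
      flags = if (length(fit$flags)) paste(fit$flags, collapse = ";")
              else NA_character_)
  }
  tab <- bind_rows(rows)

  rules <- character()
  cand <- tab %>% filter(.data$converged)
  rules <- c(rules, sprintf("converged candidates: K in {%s}",
                            paste(cand$K, collapse = ", ")))
  dropped <- cand %>% filter(.data$K > 1, .data$entropy < 0.8)
  if (nrow(dropped) > 0) {
    rules <- c(rules, sprintf(
      "dropped K = %s: entropy below 0.8 required to prefer K > 1",
      paste(dropped$K, collapse = ", ")))
  }
  cand <- cand %>% filter(.data$K == 1 | .data$entropy >= 0.8)
  if (nrow(cand) == 0) {
    recommended <- 1L
    rules <- c(rules, "no candidate converged; defaulting to K = 1")
  } else {
    recommended <- cand %>%
      filter(.data$bic == min(.data$bic)) %>%
      pull("K") %>% min()
    rules <- c(rules, sprintf(
      "smallest K attaining minimum BIC among candidates: K = %d",
      recommended))
  }
  lrt_note <- tab %>% filter(.data$K == recommended) %>% pull("vlmr_p")
  if (recommended > 1 && length(lrt_note) && !is.na(lrt_note) &&
      lrt_note > 0.05) {
    rules <- c(rules, sprintf(
      paste0("advisory: adjusted LRT could not reject K = %d at 0.05 ",
             "(p = %.3f); retained on BIC/entropy grounds"),
      recommended - 1L, lrt_note))
  }
  structure(list(table = tab, fits = fits,
                 recommended_K = as.integer(recommended), rules = rules),
            class = "gmm_enumeration")
}

#' @export
print.gmm_enumeration <- function(x, ...) {
  cat("Class enumeration\n")
  print(as.data.frame(x$table), digits = 5, row.names = FALSE)
  cat("recommended K:", x$recommended_K, "\n")
  for (r in x$rules) cat("  -", r, "\n")
  invisible(x)
}
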