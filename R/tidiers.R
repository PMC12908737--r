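#' Tidy a growth mixture fit into a parameter table
#'
#' @param x A [fit_gmm()] object.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `class` (NA for
#'   shared parameters), `estimate`.
#' @method tidy gmm_fit
#' @export
tidy.gmm_fit <- function(x, ...) {
  K <- x$spec$K; q <- ncol(x$params$mu)
  growth_names <- c("intercept", "slope", "quadratic", "cubic")[seq_len(q)]
  bind_rows(
    tibble(term = "proportion", class = seq_len(K),
           estimate = x$params$pi),
    purrr::map_dfr(seq_len(q), function(j) {
      tibble(term = paste0("mean_", growth_names[j]), class = seq_len(K),
             estimate = x$params$mu[, j])
    }),
    purrr::map_dfr(seq_len(q), function(j) {
      purrr::map_dfr(seq_len(j), function(i) {
        tibble(term = sprintf("psi_%s.%s", growth_names[i],
                              growth_names[j]),
               class = NA_integer_, estimate = x$params$psi[i, j])
      })
    }),
    tibble(term = sprintf("theta_occ%d", seq_along(x$params$theta)),
           class = NA_integer_, estimate = x$params$theta)
  )
}

#' One-row summary of a growth mixture fit
#'
#' @param x A [fit_gmm()] object.
#' @param ... Unused.
#' @return Tibble with `K`, `n`, `free_parameters`, `loglik`, `aic`, `bic`,
#'   `entropy`, `converged`, `replicated`.
#' @method glance gmm_fit
#' @export
glance.gmm_fit <- function(x, ...) {
  p <- count_free_parameters(x$spec)
  tibble(K = x$spec$K, n = x$n, free_parameters = p, loglik = x$loglik,
         aic = aic(x$loglik, p), bic = bic(x$loglik, p, x$n),
         entropy = entropy(x), converged = x$converged,
         replicated = isTRUE(x$starts_report$replicated))
}

#' Tidy a class-enumeration result
#'
#' @param x A [enumerate_classes()] object.
#' @param ... Unused.
#' @return The selection table: one row per candidate K.
#' @method tidy gmm_enumeration
#' @export
tidy.gmm_enumeration <- function(x, ...) x$table

#' One-row summary of a class enumeration
#'
#' @param x A [enumerate_classes()] object.
#' @param ... Unused.
#' @return Tibble with `recommended_K`, `k_max`, and the recommended
#'   model's `bic` and `entropy`.
#' @method glance gmm_enumeration
#' @export
glance.gmm_enumeration <- function(x, ...) {
  row <- x$table %>% filter(.data$K == x$recommended_K)
  tibble(recommended_K = x$recommended_K, k_max = max(x$table$K),
         bic = row$bic, entropy = row$entropy)
}
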