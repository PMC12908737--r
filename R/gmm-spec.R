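#' Specify a latent growth mixture model
#'
#' Describes a finite mixture of polynomial latent growth curves over `T`
#' occasions. Occasions are coded `t = 0, 1, ..., T-1`, so the intercept is
#' status at the first occasion (post-transplant year 1). The loading matrix
#' has row `t` equal to `(1, t, t^2, ...)`. The default — linear growth,
#' growth-factor covariance and occasion-specific residual variances shared
#' across classes, class-specific means only — is the structure whose free
#' parameters count `2K + (K-1) + 3 + T`.
#'
#' @param K Number of latent classes (>= 1).
#' @param n_occasions Number of measurement occasions `T`.
#' @param order Polynomial order of growth: 1 = linear (default). Orders 2
#'   and 3 are accepted but fragile in practice: with short panels they
#'   routinely fail to converge or produce non-positive-definite class
#'   covariance matrices.
#' @param variance_structure `"shared"` (class-invariant growth-factor
#'   covariance, default). `"class-varying"` is accepted by the constructor
#'   for forward compatibility but not implemented by the estimator.
#' @param residual_structure `"occasion"` (occasion-specific diagonal
#'   residual variances, default) or `"homoscedastic"`.
#' @return A list of class `"growth_spec"`.
#' @examples
#' count_free_parameters(growth_spec(K = 2, n_occasions = 10)) # 18
#' @export
growth_spec <- function(K = 2L, n_occasions = 10L, order = 1L,
                        variance_structure = c("shared", "class-varying"),
                        residual_structure = c("occasion",
                                               "homoscedastic")) {
  variance_structure <- match.arg(variance_structure)
  residual_structure <- match.arg(residual_structure)
  K <- as.integer(K); n_occasions <- as.integer(n_occasions)
  order <- as.integer(order)
  stopifnot(K >= 1, order >= 1, n_occasions >= order + 1)
  q <- order + 1L
  lambda <- outer(0:(n_occasions - 1L), 0:(order), `^`)
  structure(
    list(K = K, n_occasions = n_occasions, order = order, q = q,
         lambda = lambda, variance_structure = variance_structure,
         residual_structure = residual_structure),
    class = "growth_spec"
  )
}

#' Count free parameters of a growth mixture model
#'
#' For the default structure (class-specific growth means, shared
#' growth-factor covariance, occasion-specific residual variances) the count
#' is `K*q` class means + `(K-1)` mixing proportions + `q(q+1)/2`
#' growth-factor (co)variances + `T` residual variances, with
#' `q = order + 1`. Linear growth over 10 occasions gives 15, 18, 21 free
#' parameters for 1, 2, 3 classes.
#'
#' @param spec A [growth_spec()].
#' @return Integer parameter count.
#' @export
count_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  q <- spec$q
  n_theta <- if (spec$residual_structure == "occasion")
    spec$n_occasions else 1L
  n_var <- q * (q + 1L) / 2L
  if (spec$variance_structure == "class-varying") {
    n_var <- n_var * spec$K
    n_theta <- n_theta * spec$K
  }
  as.integer(spec$K * q + (spec$K - 1L) + n_var + n_theta)
}
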