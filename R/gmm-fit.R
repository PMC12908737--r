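#' Bundle growth-mixture parameters
#'
#' @param pi Mixing proportions (length K, positive, summing to 1).
#' @param mu Class growth-factor means, K x q matrix (q = order + 1), MLVI
#'   units.
#' @param psi Growth-factor covariance, q x q symmetric PSD, shared across
#'   classes.
#' @param theta Occasion residual variances, length T, all positive.
#' @param lambda Optional T x q loading matrix; defaults to the polynomial
#'   loadings `(1, t, t^2, ...)`, `t = 0..T-1`, with `T = length(theta)`.
#' @return List of class `"gmm_params"`.
#' @export
gmm_params <- function(pi, mu, psi, theta, lambda = NULL) {
  mu <- rbind(mu)
  K <- length(pi); q <- ncol(mu)
  if (abs(sum(pi) - 1) > 1e-8 || any(pi <= 0)) {
    abort("`pi` must be strictly positive and sum to 1.",
          class = "adheretraj_config_error")
  }
  stopifnot(nrow(mu) == K, all(dim(psi) == q), all(theta > 0))
  if (!isSymmetric(unname(psi)) ||
      min(eigen(psi, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    abort("`psi` must be symmetric positive semidefinite.",
          class = "adheretraj_config_error")
  }
  if (is.null(lambda)) {
    lambda <- outer(0:(length(theta) - 1L), 0:(q - 1L), `^`)
  }
  stopifnot(nrow(lambda) == length(theta), ncol(lambda) == q)
  structure(list(pi = as.numeric(pi), mu = unname(mu), psi = unname(psi),
                 theta = as.numeric(theta), lambda = unname(lambda)),
            class = "gmm_params")
}

as_gmm_params <- function(x) {
  if (inherits(x, "gmm_fit")) return(x$params)
  if (inherits(x, "gmm_params")) return(x)
  if (is.list(x) && all(c("pi", "mu", "psi", "theta") %in% names(x))) {
    return(gmm_params(x$pi, x$mu, x$psi, x$theta, x$lambda))
  }
  abort("Expected a `gmm_fit`, `gmm_params`, or parameter list.",
        class = "adheretraj_config_error")
}

panel_matrices <- function(panel, n_occasions = NULL) {
  m <- as_mlvi_matrix(panel)
  if (!is.null(n_occasions) && ncol(m$y) != n_occasions) {
    if (ncol(m$y) > n_occasions) {
      abort("Panel has more occasions than the model specification.",
            class = "adheretraj_config_error")
    }
    pad <- n_occasions - ncol(m$y)
    m$y <- cbind(m$y, matrix(NA_real_, nrow(m$y), pad))
    m$mask <- cbind(m$mask, matrix(FALSE, nrow(m$mask), pad))
  }
  empty <- rowSums(m$mask) == 0
  if (any(empty)) {
    abort(sprintf("Patient(s) with no observed MLVI cell: %s",
                  paste(head(rownames(m$y)[empty], 5), collapse = ", ")),
          class = "adheretraj_data_error")
  }
  m
}

call_em <- function(y, mask, params, max_iter, tol,
                    theta_floor = 1e-6, pi_floor = NULL,
                    theta_pooled = FALSE) {
  if (is.null(pi_floor)) pi_floor <- 1 / (10 * nrow(y))
  y0 <- y; y0[!mask] <- 0
  .gmm_em_cpp(y0, mask * 1L, params$lambda, params$pi, params$mu,
              params$psi, params$theta, as.integer(max_iter), tol,
              theta_floor, pi_floor, theta_pooled, rownames(y))
}

#' Observed-data marginal log-likelihood of a growth mixture model
#'
#' Sums, over patients, the log of the mixture density of the patient's
#' observed occasions: each class contributes a multivariate normal with
#' mean `Lambda mu_k` and covariance `Lambda Psi Lambda' + diag(theta)`,
#' restricted to the observed rows (the missing-completely-at-random
#' observed-data likelihood).
#'
#' @param params A [gmm_params()], [fit_gmm()] result, or plain parameter
#'   list.
#' @param panel An [mlvi_panel()]; every patient needs at least one observed
#'   cell.
#' @return The log-likelihood (scalar).
#' @export
marginal_loglik <- function(params, panel) {
  params <- as_gmm_params(params)
  m <- panel_matrices(panel, length(params$theta))
  call_em(m$y, m$mask, params, max_iter = 0L, tol = 0)$loglik
}

#' Posterior class probabilities (E-step)
#'
#' Bayes-rule responsibilities `p_ik = pi_k f_k(y_i) / sum_j pi_j f_j(y_i)`
#' evaluated on each patient's observed occasions, computed in log space.
#'
#' @inheritParams marginal_loglik
#' @return n x K matrix of posterior probabilities; rows (named by patient
#'   id) sum to 1.
#' @export
e_step <- function(params, panel) {
  params <- as_gmm_params(params)
  m <- panel_matrices(panel, length(params$theta))
  r <- call_em(m$y, m$mask, params, max_iter = 0L, tol = 0)$resp
  dimnames(r) <- list(rownames(m$y), NULL)
  r
}

ols_growth <- function(y, mask, lambda) {
  q <- ncol(lambda)
  t(vapply(seq_len(nrow(y)), function(i) {
    o <- which(mask[i, ])
    if (length(o) >= q) {
      qr.coef(qr(lambda[o, , drop = FALSE]), y[i, o])
    } else {
      c(mean(y[i, o]), rep(0, q - 1))
    }
  }, numeric(q)))
}

init_start <- function(b, y, mask, lambda, K, random = TRUE) {
  n <- nrow(b); q <- ncol(b)
  scl <- apply(b, 2, sd); scl[!is.finite(scl) | scl < 1e-8] <- 1
  if (K == 1L) {
    assign <- rep(1L, n)
  } else if (!random) {
    # deterministic split by intercept rank for the reference start
    assign <- as.integer(cut(rank(b[, 1], ties.method = "first"), K))
  } else {
    bs <- sweep(b, 2, scl, "/")
    ctr <- bs[sample.int(n, K), , drop = FALSE]
    d2 <- sapply(seq_len(K), function(k)
      rowSums(sweep(bs, 2, ctr[k, ])^2))
    assign <- max.col(-d2, ties.method = "first")
  }
  mu <- t(sapply(seq_len(K), function(k) {
    idx <- which(assign == k)
    if (length(idx) == 0) idx <- sample.int(n, max(2L, n %/% 10L))
    colMeans(b[idx, , drop = FALSE])
  }))
  mu <- matrix(mu, nrow = K)
  if (random && K > 1L) mu <- mu + rnorm(K * q, 0, 0.25 * rep(scl, each = K))
  pi <- pmax(tabulate(assign, K) / n, 0.05); pi <- pi / sum(pi)
  psi <- var(b - mu[assign, , drop = FALSE]) + diag(1e-4, q)
  resid <- y - b %*% t(lambda)
  th <- apply(resid * ifelse(mask, 1, NA), 2, var, na.rm = TRUE)
  pooled <- mean(th, na.rm = TRUE)
  if (!is.finite(pooled) || pooled < 1e-4) pooled <- 0.05
  th[!is.finite(th) | th < 1e-4] <- pooled
  gmm_params(pi, mu, psi, th, lambda)
}

canonicalize <- function(pi, mu, resp) {
  ord <- order(mu[, 1], mu[, min(2, ncol(mu))])
  list(pi = pi[ord], mu = mu[ord, , drop = FALSE],
       resp = resp[, ord, drop = FALSE])
}

#' Fit a growth mixture model by EM with multiple random starts
#'
#' Maximum-likelihood estimation of a finite mixture of linear latent growth
#' curves on an MLVI panel with missing occasions. Initial values come from
#' perturbed k-means-style splits of patient-level OLS growth estimates;
#' `n_starts` initializations are run to a loose tolerance, the best
#' `n_final` are carried to tight convergence, and the best final solution
#' is returned with a replication report (how many final solutions reached
#' the best log-likelihood within 1e-4). Classes are relabelled so class 1
#' has the lowest intercept mean (the adherent, low-MLVI trajectory).
#'
#' Hitting a variance floor or an empty class marks the fit `converged =
#' FALSE` with a flag (`"residual-variance-floor"`,
#' `"nonpositive-definite-growth-covariance"`, `"empty-class"`) and raises a
#' warning rather than masking degeneracy. If no start reaches the loose
#' tolerance at all, an error with diagnostics is thrown.
#'
#' @param panel An [mlvi_panel()] (typically yearly cadence, filtered to a
#'   minimum number of observed years).
#' @param spec A [growth_spec()].
#' @param n_starts Number of random initializations (stage 1).
#' @param n_final Number of best stage-1 solutions carried to tight
#'   convergence.
#' @param seed Integer seed governing all initialization randomness.
#' @param tol_loose,tol_final Relative log-likelihood change tolerances for
#'   the two stages.
#' @param max_iter_loose,max_iter Iteration caps for the two stages (EM on
#'   this model partitions variance between `Psi` and `theta` and converges
#'   linearly but slowly, so the final cap is generous).
#' @return An object of class `"gmm_fit"`: `params` ([gmm_params()]),
#'   `loglik`, `responsibilities` (n x K), `converged`, `flags`,
#'   `starts_report`, `spec`, `n`, `panel`.
#' @seealso [enumerate_classes()], [simulate_from_model()]
#' @export
fit_gmm <- function(panel, spec = growth_spec(2L), n_starts = 200L,
                    n_final = 50L, seed = 1L, tol_loose = 1e-6,
                    tol_final = 1e-8, max_iter_loose = 100L,
                    max_iter = 5000L) {
  stopifnot(inherits(spec, "growth_spec"), n_final <= n_starts)
  if (spec$variance_structure == "class-varying") {
    abort(paste0("Class-varying growth-factor covariance is not implemented;",
                 " use the shared (class-invariant) structure."),
          class = "adheretraj_config_error")
  }
  if (nrow(panel) == 0) {
    abort("Cannot fit on an empty panel.", class = "adheretraj_data_error")
  }
  m <- panel_matrices(panel, spec$n_occasions)
  n <- nrow(m$y); K <- spec$K
  pooled <- spec$residual_structure == "homoscedastic"
  b <- ols_growth(m$y, m$mask, spec$lambda)
  if (K == 1L) n_starts <- n_final <- 1L

  loose <- purrr::map(seq_len(n_starts), function(s) {
    p0 <- withr::with_seed(seed + s, init_start(b, m$y, m$mask, spec$lambda,
                                                K, random = (s > 1)))
    r <- call_em(m$y, m$mask, p0, max_iter_loose, tol_loose,
                 theta_pooled = pooled)
    r
  })
  ll_loose <- purrr::map_dbl(loose, "loglik")
  if (all(!is.finite(ll_loose))) {
    abort("No start produced a finite log-likelihood.",
          class = "adheretraj_convergence_error")
  }
  carry <- order(ll_loose, decreasing = TRUE)[seq_len(n_final)]
  finals <- purrr::map(carry, function(i) {
    p <- gmm_params(loose[[i]]$pi, loose[[i]]$mu, loose[[i]]$psi,
                    loose[[i]]$theta, spec$lambda)
    call_em(m$y, m$mask, p, max_iter, tol_final, theta_pooled = pooled)
  })
  ll_final <- purrr::map_dbl(finals, "loglik")
  if (!any(purrr::map_lgl(finals, "converged"))) {
    abort(
      sprintf(paste0("No start converged within %d iterations (best ",
                     "log-likelihood %.4f); consider more starts or a ",
                     "simpler model."), max_iter, max(ll_final)),
      class = "adheretraj_convergence_error")
  }
  best <- finals[[which.max(ll_final)]]
  flags <- as.character(best$flags)
  degenerate <- any(flags %in% c("residual-variance-floor",
                                 "nonpositive-definite-growth-covariance",
                                 "empty-class"))
  if (degenerate) {
    warn(sprintf(paste0("Degenerate solution (%s): latent-class covariance ",
                        "floored or class emptied; fit marked not ",
                        "converged."), paste(flags, collapse = ", ")))
  }
  can <- canonicalize(best$pi, best$mu, best$resp)
  params <- gmm_params(can$pi, can$mu, best$psi, best$theta, spec$lambda)
  resp <- can$resp
  dimnames(resp) <- list(rownames(m$y), NULL)
  n_rep <- sum(abs(ll_final - max(ll_final)) < 1e-4)
  starts_report <- list(
    seed = seed,
    n_starts = n_starts, n_final = n_final,
    loose_loglik = ll_loose,
    final = tibble(start = carry, loglik = ll_final,
                   converged = purrr::map_lgl(finals, "converged")),
    n_replicated = n_rep,
    replicated = n_final >= 2 && n_rep >= 2
  )
  structure(
    list(params = params, loglik = best$loglik, responsibilities = resp,
         converged = best$converged && !degenerate, flags = flags,
         starts_report = starts_report, spec = spec, n = n, panel = panel),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Growth mixture fit: K = %d, n = %d, T = %d\n", x$spec$K,
              x$n, x$spec$n_occasions))
  cat(sprintf("  loglik %.3f | converged: %s%s\n", x$loglik,
              x$converged,
              if (length(x$flags)) paste0(" [", paste(x$flags,
                                                      collapse = ", "), "]")
              else ""))
  cat("  pi:", paste(sprintf("%.3f", x$params$pi), collapse = " "), "\n")
  cat("  intercepts:", paste(sprintf("%.3f", x$params$mu[, 1]),
                             collapse = " "),
      "| slopes:", paste(sprintf("%.3f", x$params$mu[, 2]), collapse = " "),
      "\n")
  if (x$spec$K > 1) {
    cat(sprintf("  replicated best loglik: %s (%d/%d final starts)\n",
                x$starts_report$replicated, x$starts_report$n_replicated,
                x$starts_report$n_final))
  }
  invisible(x)
}

#' Simulate an MLVI panel from fitted mixture parameters
#'
#' Draws classes, growth factors, and occasion residuals per the model and
#' applies a missingness mask, either copied from an existing panel (the
#' parametric-bootstrap convention) or generated completely at random from
#' per-occasion missingness rates. Any patient left with no observed
#' occasion has occasion 1 forced observed so the observed-data likelihood
#' stays defined.
#'
#' @param params A [gmm_params()] / [fit_gmm()] result.
#' @param n Number of patients to draw.
#' @param missing_mask_source Either a logical matrix (rows recycled by
#'   resampling if `nrow != n`), an [mlvi_panel()] whose mask is copied, or
#'   a numeric vector of per-occasion missingness probabilities; `NULL`
#'   means fully observed.
#' @param seed Integer seed.
#' @return An [mlvi_panel()]-classed tibble (yearly cadence); the generating
#'   class of each patient is kept in `attr(, "sim_class")`.
#' @export
simulate_from_model <- function(params, n, missing_mask_source = NULL,
                                seed = 1L) {
  params <- as_gmm_params(params)
  withr::with_seed(seed, {
    T_ <- length(params$theta); K <- length(params$pi)
    z <- sample.int(K, n, replace = TRUE, prob = params$pi)
    eta <- MASS::mvrnorm(n, mu = rep(0, ncol(params$mu)),
                         Sigma = params$psi)
    eta <- matrix(eta, ncol = ncol(params$mu)) + params$mu[z, , drop = FALSE]
    y <- eta %*% t(params$lambda) +
      matrix(rnorm(n * T_, sd = rep(sqrt(params$theta), each = n)), n, T_)
    src <- missing_mask_source
    if (is.null(src)) {
      mask <- matrix(TRUE, n, T_)
    } else if (inherits(src, "mlvi_panel")) {
      mask <- as_mlvi_matrix(src)$mask
    } else if (is.matrix(src)) {
      mask <- src
    } else {
      mask <- matrix(runif(n * T_) >= rep(as.numeric(src), each = n), n, T_)
    }
    if (ncol(mask) != T_) {
      abort(sprintf("Missingness mask has %d occasions; the model has %d.",
                    ncol(mask), T_), class = "adheretraj_config_error")
    }
    if (nrow(mask) != n) {
      mask <- mask[sample.int(nrow(mask), n, replace = TRUE), , drop = FALSE]
    }
    mask[rowSums(mask) == 0, 1] <- TRUE
    ids <- sprintf("sim_%05d", seq_len(n))
    cells <- which(mask, arr.ind = TRUE)
    panel <- tibble(patient_id = ids[cells[, 1]],
                    occasion = as.integer(cells[, 2]),
                    mlvi = y[cells],
                    n_troughs = NA_integer_) %>%
      arrange(.data$patient_id, .data$occasion)
    out <- new_mlvi_panel(panel, ids, "yearly", T_)
    attr(out, "sim_class") <- setNames(z, ids)
    out
  })
}
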