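# Small cohorts and panels built in code, shared across test files.

suppressPackageStartupMessages({
  library(lubridate) # calendar arithmetic in windowing oracles
  library(tibble)
})

small_config <- function(seed = 1, n = 40, ...) {
  synth_config(n_patients = n, seed = seed, ...)
}

small_cohort <- function(seed = 1, n = 40, ...) {
  synth_cohort(small_config(seed = seed, n = n, ...))
}

# a study-scale analysis panel: generate, yearly MLVI, >= 4 observed years
analysis_panel <- function(seed = 1, n = 181) {
  co <- synth_cohort(synth_config(n_patients = n, seed = seed))
  panel <- mlvi_panel(co$troughs, co$patients)
  list(panel = minimum_years_filter(panel, 4), cohort = co)
}

# hand-rolled panel from explicit cells
panel_from_cells <- function(patient_id, occasion, mlvi, n_occasions = 10L,
                             patient_ids = sort(unique(patient_id))) {
  cells <- tibble::tibble(patient_id = patient_id,
                          occasion = as.integer(occasion), mlvi = mlvi,
                          n_troughs = 3L)
  adheretraj:::new_mlvi_panel(cells, patient_ids, "yearly", n_occasions)
}

# independent dense multivariate-normal log density (no shortcuts shared
# with the package: explicit inversion and determinant)
dmvnorm_log_oracle <- function(y, mu, sigma) {
  k <- length(y)
  -0.5 * (k * log(2 * pi) + determinant(sigma, logarithm = TRUE)$modulus +
            t(y - mu) %*% solve(sigma) %*% (y - mu))[1]
}

# brute-force observed-data mixture loglik for a panel matrix with NAs
loglik_oracle <- function(y, pi, mu, psi, theta, lambda) {
  n <- nrow(y)
  total <- 0
  for (i in seq_len(n)) {
    o <- which(!is.na(y[i, ]))
    lo <- lambda[o, , drop = FALSE]
    sig <- lo %*% psi %*% t(lo) + diag(theta[o], length(o))
    dens <- sum(vapply(seq_along(pi), function(k) {
      pi[k] * exp(dmvnorm_log_oracle(y[i, o], as.numeric(lo %*% mu[k, ]),
                                     sig))
    }, numeric(1)))
    total <- total + log(dens)
  }
  total
}

resp_oracle <- function(y, pi, mu, psi, theta, lambda) {
  out <- apply(y, 1, function(yi) {
    o <- which(!is.na(yi))
    lo <- lambda[o, , drop = FALSE]
    sig <- lo %*% psi %*% t(lo) + diag(theta[o], length(o))
    w <- vapply(seq_along(pi), function(k) {
      pi[k] * exp(dmvnorm_log_oracle(yi[o], as.numeric(lo %*% mu[k, ]), sig))
    }, numeric(1))
    w / sum(w)
  })
  if (is.null(dim(out))) matrix(out, ncol = 1) else t(out)
}

# exact Fisher two-sided p by direct enumeration of the hypergeometric
# support (central distribution, point-probability criterion)
fisher_p_oracle <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); kk <- sum(tab[, 1])
  support <- max(0, kk - n2):min(kk, m)
  probs <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n2, kk - x) - lchoose(m + n2, kk))
  }, numeric(1))
  obs <- probs[match(tab[1, 1], support)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
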