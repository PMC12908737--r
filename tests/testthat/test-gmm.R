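test_that("free-parameter counts follow the mixture structure", {
  expect_identical(count_free_parameters(growth_spec(1, 10)), 15L)
  expect_identical(count_free_parameters(growth_spec(2, 10)), 18L)
  expect_identical(count_free_parameters(growth_spec(3, 10)), 21L)
  expect_identical(count_free_parameters(growth_spec(1, 4)), 9L)
  expect_identical(
    count_free_parameters(growth_spec(2, 10,
                                      residual_structure = "homoscedastic")),
    9L)
  # counts strictly increase with K
  counts <- vapply(1:4, function(k)
    count_free_parameters(growth_spec(k, 10)), integer(1))
  expect_true(all(diff(counts) > 0))
})

test_that("marginal loglik matches closed forms and a brute-force oracle", {
  # K = 1, T = 1, y at the mean: -0.5 log(2 pi sigma^2)
  p1 <- gmm_params(1, matrix(c(2, 0), 1), diag(c(0, 0)), theta = 0.5,
                   lambda = matrix(c(1, 0), 1))
  panel1 <- panel_from_cells("A", 1, 2, n_occasions = 1)
  expect_equal(marginal_loglik(p1, panel1), -0.5 * log(2 * pi * 0.5),
               tolerance = 1e-10)

  # degenerate mixture pi = (1, 0) equals the 1-class loglik
  withr::with_seed(4, {
    y <- matrix(rnorm(18, 2), 6, 3)
    y[cbind(c(2, 5), c(3, 1))] <- NA
  })
  cells <- which(!is.na(y), arr.ind = TRUE)
  panel <- panel_from_cells(sprintf("p%02d", cells[, 1]), cells[, 2],
                            y[cells], n_occasions = 3)
  lam <- cbind(1, 0:2)
  psi <- matrix(c(0.4, 0.05, 0.05, 0.1), 2)
  th <- c(0.3, 0.2, 0.25)
  p_one <- gmm_params(1, matrix(c(2, 0.1), 1), psi, th, lam)
  p_two <- gmm_params(c(1 - 1e-12, 1e-12),
                      rbind(c(2, 0.1), c(5, -1)), psi, th, lam)
  expect_equal(marginal_loglik(p_two, panel), marginal_loglik(p_one, panel),
               tolerance = 1e-6)

  # brute-force oracle on random small instances
  for (seed in 1:5) {
    withr::with_seed(seed, {
      K <- sample(1:3, 1)
      pi_ <- runif(K) + 0.2; pi_ <- pi_ / sum(pi_)
      mu <- matrix(rnorm(2 * K, 2), K)
      a <- matrix(rnorm(4, sd = 0.4), 2)
      psi_r <- a %*% t(a) + diag(0.05, 2)
      th_r <- runif(3, 0.1, 0.5)
      yr <- matrix(rnorm(24, 2), 8, 3)
      yr[sample(24, 5)] <- NA
    })
    yr[rowSums(!is.na(yr)) == 0, 1] <- 0
    cr <- which(!is.na(yr), arr.ind = TRUE)
    pr <- panel_from_cells(sprintf("p%02d", cr[, 1]), cr[, 2], yr[cr],
                           n_occasions = 3)
    pars <- gmm_params(pi_, mu, psi_r, th_r, lam)
    expect_equal(marginal_loglik(pars, pr),
                 loglik_oracle(yr, pi_, mu, psi_r, th_r, lam),
                 tolerance = 1e-8)
    expect_equal(unname(e_step(pars, pr)),
                 unname(resp_oracle(yr, pi_, mu, psi_r, th_r, lam)),
                 tolerance = 1e-8)
  }
})

test_that("E-step responsibilities behave at the boundaries", {
  lam <- cbind(1, 0:2)
  psi <- diag(c(0.2, 0.05))
  th <- rep(0.2, 3)
  panel <- panel_from_cells(rep("A", 3), 1:3, c(2, 2.1, 2.2),
                            n_occasions = 3)
  # K = 1: responsibility exactly 1
  expect_equal(as.numeric(e_step(gmm_params(1, matrix(c(2, 0), 1), psi, th,
                                            lam), panel)), 1)
  # symmetric two-class setup, patient equidistant from both means
  pars <- gmm_params(c(0.5, 0.5), rbind(c(1, 0), c(3, 0)), psi, th, lam)
  pan_mid <- panel_from_cells(rep("A", 3), 1:3, c(2, 2, 2), n_occasions = 3)
  expect_equal(as.numeric(e_step(pars, pan_mid)), c(0.5, 0.5),
               tolerance = 1e-12)
  # rows sum to one even for extreme outliers (log-space computation)
  pan_far <- panel_from_cells(rep("A", 3), 1:3, c(80, 90, 100),
                              n_occasions = 3)
  expect_equal(sum(e_step(pars, pan_far)), 1, tolerance = 1e-10)
})

test_that("EM increases the log-likelihood and reports consistent results", {
  ap <- analysis_panel(seed = 2, n = 120)
  fit <- fit_gmm(ap$panel, growth_spec(2), n_starts = 8, n_final = 2,
                 seed = 5)
  expect_true(fit$converged)
  # responsibilities rows sum to 1
  expect_equal(rowSums(fit$responsibilities),
               setNames(rep(1, fit$n), rownames(fit$responsibilities)),
               tolerance = 1e-10)
  # reported loglik equals an independent evaluation at the parameters
  expect_equal(fit$loglik, marginal_loglik(fit$params, ap$panel),
               tolerance = 1e-8)
  # canonical order: class 1 has the lower intercept
  expect_true(diff(fit$params$mu[, 1]) > 0)
  # determinism
  fit2 <- fit_gmm(ap$panel, growth_spec(2), n_starts = 8, n_final = 2,
                  seed = 5)
  expect_identical(fit$loglik, fit2$loglik)
  expect_identical(fit$starts_report$final, fit2$starts_report$final)
})

test_that("EM trace is monotone on every start", {
  ap <- analysis_panel(seed = 13, n = 80)
  m <- as_mlvi_matrix(ap$panel)
  y0 <- m$y; y0[!m$mask] <- 0
  spec <- growth_spec(2)
  b <- adheretraj:::ols_growth(m$y, m$mask, spec$lambda)
  for (s in 1:5) {
    p0 <- withr::with_seed(s, adheretraj:::init_start(b, m$y, m$mask,
                                                      spec$lambda, 2))
    r <- adheretraj:::call_em(y0, m$mask, p0, max_iter = 200, tol = 1e-8)
    expect_true(all(diff(r$trace) > -1e-8))
  }
})

test_that("label permutation leaves the likelihood unchanged", {
  ap <- analysis_panel(seed = 3, n = 60)
  lam <- growth_spec(2)$lambda
  pars <- gmm_params(c(0.9, 0.1), rbind(c(1.5, 0), c(3.3, 0)),
                     diag(c(0.0625, 0.0009)), rep(0.05, 10), lam)
  perm <- gmm_params(c(0.1, 0.9), rbind(c(3.3, 0), c(1.5, 0)),
                     diag(c(0.0625, 0.0009)), rep(0.05, 10), lam)
  expect_equal(marginal_loglik(pars, ap$panel),
               marginal_loglik(perm, ap$panel), tolerance = 1e-10)
})

test_that("one-class fits recover the generating growth means", {
  pars <- gmm_params(1, matrix(c(2, 0.1), 1), diag(c(0.3, 0.01)),
                     rep(0.2, 6))
  sim <- simulate_from_model(pars, 500, rep(0.1, 6), seed = 8)
  fit <- fit_gmm(sim, growth_spec(1, 6), seed = 2)
  # 3-SE band using the fitted growth-factor covariance
  se <- sqrt(diag(fit$params$psi) / 500)
  expect_lt(abs(fit$params$mu[1] - 2), 3 * se[1] + 0.05)
  expect_lt(abs(fit$params$mu[2] - 0.1), 3 * se[2] + 0.01)
})

test_that("two-class fits recover labels under strong class separation", {
  ap <- analysis_panel(seed = 17)
  fit <- fit_gmm(ap$panel, growth_spec(2), n_starts = 16, n_final = 4,
                 seed = 4)
  cls <- classify(fit)
  truth <- ap$cohort$truth$class[match(cls$assignment$patient_id,
                                       ap$cohort$truth$patient_id)]
  expect_gte(mean(cls$assignment$class == truth), 0.95)
  expect_true(fit$starts_report$replicated)
})

test_that("simulate_from_model honours the parameters", {
  lam <- growth_spec(2, n_occasions = 4)$lambda
  # zero variances: trajectories lie exactly on Lambda mu
  p0 <- gmm_params(c(0.5, 0.5), rbind(c(1, 0.5), c(3, -0.2)),
                   matrix(0, 2, 2), rep(1e-12, 4), lam)
  sim <- simulate_from_model(p0, 50, seed = 6)
  z <- attr(sim, "sim_class")
  m <- as_mlvi_matrix(sim)
  for (k in 1:2) {
    rows <- m$y[names(z)[z == k], , drop = FALSE]
    expected <- as.numeric(lam %*% p0$mu[k, ])
    expect_equal(unname(rows),
                 matrix(expected, nrow(rows), 4, byrow = TRUE),
                 tolerance = 1e-5)
  }
  # class shares converge to pi
  p1 <- gmm_params(c(0.7, 0.3), rbind(c(1, 0), c(3, 0)), diag(c(0.1, 0.01)),
                   rep(0.1, 4), lam)
  simn <- simulate_from_model(p1, 20000, seed = 7)
  shares <- as.numeric(table(attr(simn, "sim_class"))) / 20000
  expect_lt(max(abs(shares - c(0.7, 0.3))), 0.01)
  # mask copied from a source panel has the same missingness pattern
  src <- analysis_panel(seed = 19, n = 40)$panel
  p10 <- gmm_params(c(0.7, 0.3), rbind(c(1, 0), c(3, 0)),
                    diag(c(0.1, 0.01)), rep(0.1, 10))
  sim_m <- simulate_from_model(p10, length(attr(src, "patient_ids")),
                               missing_mask_source = src, seed = 8)
  expect_identical(unname(as_mlvi_matrix(sim_m)$mask),
                   unname(as_mlvi_matrix(src)$mask))
  # occasion-count mismatch between mask and model is rejected
  expect_error(simulate_from_model(p1, 40, missing_mask_source = src,
                                   seed = 8), "occasions")
})

test_that("degenerate and invalid inputs fail loudly", {
  expect_error(gmm_params(c(0.5, 0.6), rbind(c(1, 0), c(2, 0)),
                          diag(2), rep(0.1, 4)), "sum to 1")
  ap <- analysis_panel(seed = 23, n = 40)
  expect_error(fit_gmm(ap$panel,
                       growth_spec(2, variance_structure = "class-varying")),
               "not implemented")
  expect_error(fit_gmm(ap$panel[0, ], growth_spec(2)), "empty panel")
  # identical rows: variance floors are flagged, not silently absorbed
  flat <- panel_from_cells(rep(sprintf("p%02d", 1:12), each = 4),
                           rep(1:4, 12), rep(2, 48), n_occasions = 4)
  fit <- suppressWarnings(fit_gmm(flat, growth_spec(1, 4), seed = 1))
  expect_false(fit$converged)
  expect_true("residual-variance-floor" %in% fit$flags)
})
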