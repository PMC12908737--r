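test_that("modal classification and AvePP follow their definitions", {
  onehot <- diag(3)[c(1, 2, 3, 2), ]
  rownames(onehot) <- sprintf("p%d", 1:4)
  cl <- classify(onehot)
  expect_equal(unname(cl$avepp), diag(3))
  expect_equal(cl$counts, c(1, 2, 1))
  # exact tie goes to the lower class index
  expect_equal(classify(matrix(c(0.5, 0.5), 1))$assignment$class, 1L)
  # AvePP against a brute-force group-mean recomputation
  withr::with_seed(5, {
    p <- matrix(runif(60), 20, 3); p <- p / rowSums(p)
  })
  cl2 <- classify(p)
  modal <- apply(p, 1, which.max)
  for (j in sort(unique(modal))) {
    expect_equal(unname(cl2$avepp[j, ]),
                 colMeans(p[modal == j, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  # argmax is invariant to monotone rescaling of rows
  cl3 <- classify(p^3 / rowSums(p^3))
  expect_equal(cl3$assignment$class, cl2$assignment$class)
})

test_that("separation analysis reports ranges, gaps, and midpoints", {
  # the published two-class ranges: gap (2.10, 2.67), midpoint 2.385
  panel <- panel_from_cells(
    patient_id = sprintf("p%02d", 1:4), occasion = rep(1, 4),
    mlvi = c(1.07, 2.10, 2.67, 3.99), n_occasions = 1
  )
  labels <- tibble(patient_id = sprintf("p%02d", 1:4),
                   class = c(1, 1, 2, 2))
  rep_ <- separation_analysis(panel, labels)
  expect_false(rep_$overlap)
  expect_equal(rep_$gap_lower, 2.10)
  expect_equal(rep_$gap_upper, 2.67)
  expect_equal(rep_$threshold, 2.385)
  expect_true(rep_$threshold > rep_$gap_lower &&
                rep_$threshold < rep_$gap_upper)
  # identical single-patient classes overlap
  p2 <- panel_from_cells(c("a", "b"), c(1, 1), c(2, 2), n_occasions = 1)
  l2 <- tibble(patient_id = c("a", "b"), class = 1:2)
  expect_true(separation_analysis(p2, l2)$overlap)
  # a class with zero panel patients errors
  expect_error(
    separation_analysis(p2, tibble(patient_id = c("a", "b", "c"),
                                   class = c(1, 1, 2))),
    "zero patients")
})

test_that("Fisher exact matches enumeration and handles edge tables", {
  sym <- fisher_exact(matrix(5, 2, 2))
  expect_equal(sym$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(sym$p_value, 1)
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin is zero")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integers")
  # p-values agree with direct support enumeration on fixed margins
  for (a in 0:6) {
    tab <- matrix(c(a, 6 - a, 6 - a, a), 2, byrow = TRUE)
    expect_equal(fisher_exact(tab)$p_value, fisher_p_oracle(tab),
                 tolerance = 1e-9)
  }
})

test_that("Mann-Whitney U counts pairs like the brute-force oracle", {
  # fully disjoint samples: U = 0
  expect_equal(mann_whitney(c(1.1, 1.5, 2.0), c(2.7, 3.2))$statistic, 0)
  # tie convention: identical singletons give U = 0.5
  expect_equal(mann_whitney(1, 1)$statistic, 0.5)
  withr::with_seed(9, {
    for (i in 1:10) {
      a <- round(rnorm(8, 0, 2), 1)
      b <- round(rnorm(7, 0.5, 2), 1)
      u_brute <- sum(outer(a, b, `>`)) + 0.5 * sum(outer(a, b, `==`))
      res <- mann_whitney(a, b)
      expect_equal(res$u_a, u_brute)
      expect_equal(res$statistic, min(u_brute, 8 * 7 - u_brute))
      expect_true(res$p_value >= 0 && res$p_value <= 1)
    }
  })
})

test_that("Cliff's delta spans its range and matches the U identity", {
  expect_equal(cliffs_delta(c(1, 2), c(3, 4))$delta, -1)
  expect_equal(cliffs_delta(rep(2, 4), rep(2, 5))$delta, 0)
  withr::with_seed(10, {
    for (i in 1:10) {
      a <- rnorm(9); b <- rnorm(6, 0.3) # continuous: tie-free
      d <- cliffs_delta(a, b)
      u_b <- mann_whitney(a, b)$u_b
      expect_equal(d$delta, 1 - 2 * u_b / (9 * 6), tolerance = 1e-12)
      expect_true(d$conf_low <= d$delta && d$delta <= d$conf_high)
      expect_true(d$conf_low >= -1 && d$conf_high <= 1)
    }
  })
})

test_that("outcome rates aggregate per patient and per person-year", {
  oc <- tibble(
    patient_id = c("a", "a", "b", "b", "c"),
    post_tx_year = c(1, 2, 1, 2, 1),
    lar_hosp = c(0, 0, 1, 0, 0)
  )
  labels <- tibble(patient_id = c("a", "b", "c"), class = c(1, 1, 2))
  r <- outcome_rates(oc, labels)
  expect_equal(r$pct_any_lar, c(50, 0))
  expect_equal(r$pct_lar_per_year, c(25, 0))
  expect_equal(r$person_years, c(4, 1))
  # no events and all events
  expect_equal(outcome_rates(mutate(oc, lar_hosp = 0),
                             labels)$pct_any_lar, c(0, 0))
  expect_equal(outcome_rates(mutate(oc, lar_hosp = 1),
                             labels)$pct_lar_per_year, c(100, 100))
  expect_error(outcome_rates(oc, labels[1:2, ]), "without a class label")
  # calibration against configured class-specific rates at n = 2000
  cfg <- synth_config(n_patients = 2000, seed = 44,
                      resid_sd_by_year = rep(0.15, 4),
                      attrition_profile = c(0.1, 0.2, 0.3, 0.4))
  co <- synth_cohort(cfg)
  rr <- outcome_rates(co$outcomes,
                      tibble(patient_id = co$truth$patient_id,
                             class = co$truth$class))
  for (k in 1:2) {
    p <- cfg$lar_prob_by_class[k]
    se <- sqrt(p * (1 - p) / rr$person_years[k])
    expect_lt(abs(rr$pct_lar_per_year[k] / 100 - p), 3 * se)
  }
})

test_that("comparison tables pick the right test per variable type", {
  co <- synth_cohort(synth_config(seed = 47))
  labels <- tibble(patient_id = co$truth$patient_id,
                   class = co$truth$class)
  tab <- compare_classes(co$patients, labels, co$outcomes)
  expect_true(all(c("Insurance, public", "Functional status",
                    "LAR hospitalization, any year") %in% tab$variable))
  expect_equal(tab$test[tab$variable == "Insurance, public"],
               "Fisher exact")
  expect_equal(tab$test[tab$variable == "Functional status"],
               "Mann-Whitney U")
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  d <- tab$estimate[tab$effect == "Cliff's delta"]
  expect_true(all(abs(d) <= 1))
})
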