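test_that("single-window MLVI follows the >=3-trough sample-SD rule", {
  expect_equal(mlvi_window(c(8, 8, 8)), 0)
  expect_equal(mlvi_window(c(6, 8, 10)), 2) # ((-2)^2 + 0 + 2^2)/2 = 4
  expect_true(is.na(mlvi_window(c(5, 9))))
  expect_true(is.na(mlvi_window(numeric(0))))
  expect_error(mlvi_window(c(8, -1, 9)), "Non-positive")
  expect_equal(mlvi_window(c(6, 8, 10), divisor = "n"), 2 * sqrt(2 / 3))
})

test_that("panels round-trip the generator's latent MLVI exactly", {
  co <- small_cohort(seed = 5, n = 30)
  panel <- mlvi_panel(co$troughs, co$patients)
  lat <- attr(co$truth, "latent_mlvi")
  ret <- attr(co$truth, "retained")
  m <- as_mlvi_matrix(panel)
  expect_identical(unname(m$mask[rownames(lat), ]), unname(ret))
  cells <- which(ret, arr.ind = TRUE)
  expect_equal(m$y[rownames(lat), ][cells], lat[cells], tolerance = 1e-9)
})

test_that("every panel cell equals the sample SD of its window's troughs", {
  co <- small_cohort(seed = 6, n = 12)
  panel <- mlvi_panel(co$troughs, co$patients)
  tx <- co$patients$transplant_date[match(panel$patient_id,
                                          co$patients$patient_id)]
  for (r in seq_len(nrow(panel))) {
    lo <- tx[r] %m+% lubridate::years(panel$occasion[r] - 1)
    hi <- tx[r] %m+% lubridate::years(panel$occasion[r])
    lv <- co$troughs$level_ng_ml[co$troughs$patient_id ==
                                   panel$patient_id[r] &
                                   co$troughs$date > lo &
                                   co$troughs$date <= hi]
    expect_identical(length(lv), as.integer(panel$n_troughs[r]))
    expect_identical(sd(lv), panel$mlvi[r])
  }
})

test_that("windowing boundaries follow the half-open convention", {
  patients <- tibble::tibble(patient_id = "A",
                             transplant_date = as.Date("2012-03-01"))
  # troughs only in month 2: year-1 cell present, later years absent
  tr <- tibble::tibble(
    patient_id = "A",
    date = as.Date("2012-05-01") + c(0, 3, 9, 20),
    level_ng_ml = c(6, 8, 10, 8)
  )
  p <- mlvi_panel(tr, patients, n_occasions = 5)
  expect_equal(p$occasion, 1L)
  # trough exactly at a quarter anchor is included in that quarter
  anchor <- as.Date("2012-03-01") %m+% months(3)
  tr2 <- tibble::tibble(patient_id = "A",
                        date = c(anchor, anchor - 10, anchor - 20),
                        level_ng_ml = c(6, 8, 10))
  pq <- mlvi_panel(tr2, patients, cadence = "quarterly", n_occasions = 8)
  expect_true(1L %in% pq$occasion)
  expect_equal(pq$mlvi[pq$occasion == 1], 2)
  # the same troughs also fall in later overlapping 12-month windows
  expect_true(all(2:4 %in% pq$occasion))
})

test_that("unknown patients and bad levels are rejected", {
  patients <- tibble::tibble(patient_id = "A",
                             transplant_date = as.Date("2012-03-01"))
  tr <- tibble::tibble(patient_id = "B", date = as.Date("2012-05-01"),
                       level_ng_ml = 8)
  expect_error(mlvi_panel(tr, patients), "unknown patient")
  tr2 <- tibble::tibble(patient_id = "A",
                        date = as.Date("2012-05-01") + 0:2,
                        level_ng_ml = c(8, 0, 9))
  expect_error(mlvi_panel(tr2, patients), "Non-positive")
  empty <- mlvi_panel(tr[0, ], patients)
  expect_equal(nrow(empty), 0)
})

test_that("MLVI is scale-equivariant and shift-invariant", {
  co <- small_cohort(seed = 7, n = 10)
  base <- mlvi_panel(co$troughs, co$patients)
  for (c_ in c(0.5, 3)) {
    scaled <- co$troughs
    scaled$level_ng_ml <- scaled$level_ng_ml * c_
    ps <- mlvi_panel(scaled, co$patients)
    expect_equal(ps$mlvi, base$mlvi * c_, tolerance = 1e-12)
  }
  shifted <- co$troughs
  shifted$level_ng_ml <- shifted$level_ng_ml + 4
  expect_equal(mlvi_panel(shifted, co$patients)$mlvi, base$mlvi,
               tolerance = 1e-12)
})

test_that("eligibility filter drops short follow-up and repeat transplants", {
  patients <- tibble::tibble(
    patient_id = c("A", "B", "B", "C"),
    transplant_date = as.Date(c("2012-01-01", "2013-01-01", "2015-06-01",
                                "2014-01-01"))
  )
  troughs <- tibble::tibble(
    patient_id = c("A", "A", "B", "C"),
    date = as.Date(c("2012-02-01", "2012-04-20", "2014-01-01",
                     "2014-09-15")),
    level_ng_ml = 8
  )
  res <- eligibility_filter(patients, troughs)
  # A: troughs only in months 1-4 -> excluded; B: first transplant kept
  expect_setequal(res$patients$patient_id, c("B", "C"))
  expect_equal(res$patients$transplant_date[res$patients$patient_id == "B"],
               as.Date("2013-01-01"))
  expect_equal(res$exclusions$n[res$exclusions$reason ==
                                  "repeat transplant"], 1)
  expect_equal(res$exclusions$n[res$exclusions$reason ==
                                  "follow-up < 6 mo"], 1)
  # all-eligible input comes back unchanged with a zero tally
  ok <- eligibility_filter(res$patients, troughs)
  expect_equal(ok$patients, res$patients)
  expect_true(all(ok$exclusions$n == 0))
})

test_that("minimum-years filter matches a brute-force recount", {
  co <- small_cohort(seed = 9, n = 60)
  panel <- mlvi_panel(co$troughs, co$patients)
  f <- minimum_years_filter(panel, 4)
  by_hand <- names(which(rowSums(attr(co$truth, "retained")) >= 4))
  expect_setequal(attr(f, "patient_ids"), by_hand)
  expect_true(all(f$patient_id %in% by_hand))
  # min_years = 1 keeps every observed patient
  f1 <- minimum_years_filter(panel, 1)
  expect_setequal(attr(f1, "patient_ids"), unique(panel$patient_id))
})

test_that("missingness profile counts unobserved patient-years", {
  p <- panel_from_cells(
    patient_id = rep(c("A", "B"), each = 3),
    occasion = c(1, 2, 3, 1, 2, 3), mlvi = rep(1, 6), n_occasions = 3
  )
  expect_equal(missingness_profile(p)$missing_frac, c(0, 0, 0))
  p2 <- panel_from_cells(
    patient_id = c("A", "B", "A"), occasion = c(1, 1, 2),
    mlvi = rep(1, 3), n_occasions = 3
  )
  expect_equal(missingness_profile(p2)$missing_frac, c(0, 0.5, 1))
  # calibration against the generator's attrition profile
  cfg <- synth_config(n_patients = 600, seed = 14)
  co <- synth_cohort(cfg)
  prof <- missingness_profile(mlvi_panel(co$troughs, co$patients))
  expect_lt(max(abs(prof$missing_frac - cfg$attrition_profile)), 0.06)
})
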