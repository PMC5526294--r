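test_that("4PL fitting recovers generating parameters from noiseless standards", {
  std <- make_standards(a = 50, d = 30000, c = 500, b = 1)
  cu <- fit_standard_curve(std)
  expect_equal(cu$a, 50, tolerance = 1e-4)
  expect_equal(cu$d, 30000, tolerance = 1e-4)
  expect_equal(cu$c, 500, tolerance = 1e-4)
  expect_equal(cu$b, 1, tolerance = 1e-4)
  expect_gt(cu$r_squared, 0.999)  # passes the plate criterion

  # steeper and shallower Hill slopes
  for (b in c(0.7, 1.4)) {
    cu2 <- fit_standard_curve(make_standards(a = 20, d = 25000, c = 120, b = b))
    expect_equal(cu2$b, b, tolerance = 1e-4)
  }
  # midpoint identity: response at x = c is (a+d)/2
  expect_equal(fourpl(cu$c, cu$a, cu$d, cu$c, cu$b), (cu$a + cu$d) / 2)
  expect_error(fit_standard_curve(data.frame(concentration = c(0, 1, 2),
                                             response = c(1, 2, 3))),
               "5 distinct")
})

test_that("back-calculation inverts the curve, clamps and flags", {
  cu <- fit_standard_curve(make_standards())
  th <- qc_thresholds()
  tfrc <- th[th$analyte == "TFRC", ]
  # midpoint response inverts to c, scaled by the dilution factor
  mid <- backcalculate(cu, (cu$a + cu$d) / 2, 5000, tfrc$lloq, tfrc$uloq)
  expect_equal(mid$conc_diluted, cu$c, tolerance = 1e-8)
  expect_equal(mid$conc, cu$c * 5000, tolerance = 1e-4)
  # diluted 10 pg/mL at dilution 5000 reports 50,000 on the sample scale
  r10 <- fourpl(10, cu$a, cu$d, cu$c, cu$b)
  expect_equal(backcalculate(cu, r10, 5000, 0.49, 2000)$conc, 50000,
               tolerance = 1e-6)
  # diluted TFRC reading of 0.3 pg/mL sits below the 0.49 LLoQ
  r03 <- fourpl(0.3, cu$a, cu$d, cu$c, cu$b)
  low <- backcalculate(cu, r03, tfrc$dilution_factor, tfrc$lloq, tfrc$uloq)
  expect_true(low$below_lloq)
  expect_equal(low$conc_diluted, tfrc$lloq)  # clamped, retained
  # response outside the curve range is unquantifiable
  out <- backcalculate(cu, cu$d + 1, 5000, 0.49, 2000)
  expect_false(out$quantifiable)
  expect_true(is.na(out$conc))
})

test_that("round trip through the curve is exact inside the LoQ range", {
  cu <- fit_standard_curve(make_standards(a = 30, d = 22000, c = 800, b = 1.2))
  x <- exp(seq(log(25), log(90000), length.out = 50))
  y <- fourpl(x, cu$a, cu$d, cu$c, cu$b)
  bc <- backcalculate(cu, y, 1, 24.41, 100000)
  expect_equal(bc$conc_diluted, x, tolerance = 1e-8)
})

test_that("duplicate CV matches the closed form and is scale invariant", {
  expect_equal(duplicate_cv(100, 100), 0)
  expect_equal(duplicate_cv(90, 110), 100 * 20 / (sqrt(2) * 100))
  expect_equal(duplicate_cv(90, 110), 14.14, tolerance = 1e-3)
  cv <- duplicate_cv(100, 150)
  expect_equal(cv, 28.28, tolerance = 1e-3)
  expect_gt(cv, 20)  # exceeds the panel-wide maximum
  withr::with_seed(1, {
    for (i in 1:20) {
      a <- runif(1, 1, 100); b <- runif(1, 1, 100); k <- runif(1, 0.1, 50)
      expect_equal(duplicate_cv(k * a, k * b), duplicate_cv(a, b))
    }
  })
  expect_error(duplicate_cv(-3, 1), "non-positive")
})

test_that("plate acceptance applies all three criteria with reasons", {
  th <- qc_thresholds()
  rng <- tibble::tibble(analyte = "A1AG", pqc_lo = 500, pqc_hi = 900)
  mk_curve <- function(b, r2) {
    structure(list(a = 50, d = 30000, c = 700, b = b, r_squared = r2),
              class = "standard_curve")
  }
  pqc <- tibble::tibble(analyte = "A1AG", response_1 = 1000,
                        response_2 = 1010, conc_1 = 700, conc_2 = 705)
  ok <- accept_plate(list(A1AG = mk_curve(0.95, 0.99)), pqc, th, rng)
  expect_true(ok$accept)
  expect_length(ok$reasons, 0)
  bad_hill <- accept_plate(list(A1AG = mk_curve(1.2, 0.99)), pqc, th, rng)
  expect_false(bad_hill$accept)
  expect_match(bad_hill$reasons, "Hill slope")
  bad_r2 <- accept_plate(list(A1AG = mk_curve(0.95, 0.94)), pqc, th, rng)
  expect_false(bad_r2$accept)
  expect_match(bad_r2$reasons, "R\\^2")
  bad_pqc <- accept_plate(
    list(A1AG = mk_curve(0.95, 0.99)),
    tibble::tibble(analyte = "A1AG", response_1 = 1000, response_2 = 1010,
                   conc_1 = 2000, conc_2 = 2005), th, rng)
  expect_match(bad_pqc$reasons, "PQC concentration")
  bad_cv <- accept_plate(
    list(A1AG = mk_curve(0.95, 0.99)),
    tibble::tibble(analyte = "A1AG", response_1 = 1000, response_2 = 1500,
                   conc_1 = 700, conc_2 = 750), th, rng)
  expect_match(bad_cv$reasons, "duplicate CV")
  expect_error(accept_plate(list(A1AG = mk_curve(1, 0.99)),
                            pqc[0, ], th, rng), "PQC records missing")
})

test_that("sample acceptance filters on duplicate CV and conserves rows", {
  th <- qc_thresholds()
  rec <- tibble::tibble(
    subject_id = c("s1", "s2", "s3"),
    analyte = "CEA",
    response_1 = c(100, 100, 100),
    response_2 = c(100 * (1 + 0.19 * sqrt(2)),                    # CV ~17%
                   100 * (2 + 0.21 * sqrt(2)) / (2 - 0.21 * sqrt(2)), # CV 21%
                   101),
    conc_1 = c(50, 60, 70), conc_2 = c(52, 62, 70)
  )
  out <- accept_measures(rec, th)
  expect_setequal(out$accepted$subject_id, c("s1", "s3"))
  expect_equal(out$rejections$subject_id, "s2")
  expect_equal(out$rejections$reason, "cv_fail")
  expect_gt(out$rejections$cv, 20)
  # retained value is the mean of duplicates
  expect_equal(out$accepted$CEA[out$accepted$subject_id == "s1"], 51)
  # all-pass input conserves the subject count; no invented rows
  rec2 <- rec[c(1, 3), ]
  out2 <- accept_measures(rec2, th)
  expect_equal(nrow(out2$accepted), 2)
  expect_true(all(out2$accepted$subject_id %in% rec2$subject_id))
  empty <- accept_measures(rec[0, ], th)
  expect_equal(nrow(empty$accepted), 0)
})

test_that("plate simulation has the specified geometry and noise", {
  coh <- tiny_cohort(50, seed = 2)
  conc <- sample_concentrations(coh, tiny_panel(seed = 2))
  pl <- simulate_plates(conc, noise_cv = 0, seed = 2)
  # zero noise: duplicate pairs identical
  wide <- tidyr::pivot_wider(
    pl[pl$role == "sample", c("plate_id", "analyte", "subject_id",
                              "replicate", "response")],
    names_from = "replicate", values_from = "response")
  expect_equal(wide$`1`, wide$`2`)
  # plate count = ceiling(n / samples per plate), per panel
  expect_equal(length(unique(pl$plate_id[pl$panel == 4])), ceiling(50 / 39))
  pl2 <- simulate_plates(conc, samples_per_plate = 10, seed = 2)
  expect_equal(length(unique(pl2$plate_id[pl2$panel == 4])), ceiling(50 / 10))
  # 8 standard levels (incl. blank) and PQCs, all in duplicate
  one <- pl[pl$plate_id == pl$plate_id[1] & pl$analyte == pl$analyte[1], ]
  expect_equal(sum(one$role == "standard"), 16)
  expect_equal(sum(one$role == "pqc"), 2)
  expect_equal(sum(one$true_conc == 0 & one$role == "standard"), 2)
  expect_error(simulate_plates(conc, samples_per_plate = 45), "capacity")
  expect_error(simulate_plates(conc, noise_cv = -0.1), "non-negative")
})

test_that("end-to-end QC accepts clean plates and recovers concentrations", {
  coh <- tiny_cohort(60, seed = 9)
  conc <- sample_concentrations(coh, tiny_panel(seed = 9))
  pl <- simulate_plates(conc, noise_cv = 0.04, seed = 9)
  qc <- run_qc(pl)
  expect_true(all(qc$plate_log$accept))
  acc <- qc$concentrations
  ok <- stats::complete.cases(acc)
  m <- match(acc$subject_id, conc$subject_id)
  expect_gt(cor(log(acc$CEA[ok]), log(conc$CEA[m][ok])), 0.98)
  expect_named(qc$rejections, c("subject_id", "analyte", "cv", "reason"))
})
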