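# The benchmark values used here are the per-patient dominant frequencies
# and amplitudes of the published 11-patient PD cohort shipped in
# inst/extdata (see ?pd_cohort_table).

test_that("absolute error matches the benchmark rows and the definition", {
  expect_equal(absolute_error(4.877, 4.888), 0.011)
  expect_equal(absolute_error(1.533, 2.087), 0.554)
  expect_equal(absolute_error(3.3, 3.3), 0)
  expect_equal(absolute_error(c(1, 2), c(2, 1)), c(1, 1))
})

test_that("RMSE matches the benchmark cohort and closed forms", {
  fr <- pd_cohort_table("frequency_validation")
  expect_equal(freq_rmse(fr$f_acc_hz, fr$f_vid_hz), 0.283, tolerance = 1e-3)
  expect_equal(freq_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(freq_rmse(c(1, 3), c(2, 3)), sqrt(0.5))
  expect_error(freq_rmse(NA_real_, NA_real_), "no complete pairs")
})

test_that("Pearson correlation reproduces the benchmark and cor.test", {
  fr <- pd_cohort_table("frequency_validation")
  pf <- pearson_r(fr$f_acc_hz, fr$f_vid_hz)
  expect_identical(pf$n, 10L)
  expect_equal(round(pf$r, 2), 0.98)

  am <- pd_cohort_table("amplitude_validation")
  pa <- pearson_r(am$a_acc_cm_s2, am$a_vid_au)
  expect_equal(round_half_up(pa$r, 1), 1.0)
  expect_gt(pa$r, 0.99)

  # exact linear relation
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x)$r, 1.0)

  # r and p agree with stats::cor.test on random data
  set.seed(77)
  for (i in 1:10) {
    a <- rnorm(12); b <- 0.5 * a + rnorm(12)
    ct <- cor.test(a, b)
    pr <- pearson_r(a, b)
    expect_equal(pr$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pr$p, ct$p.value, tolerance = 1e-12)
  }

  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("Pearson r is invariant under positive affine transforms", {
  set.seed(8)
  x <- rnorm(15); y <- x + rnorm(15, sd = 0.3)
  base <- pearson_r(x, y)$r
  expect_equal(pearson_r(3 * x + 7, y)$r, base, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.1 * y - 2)$r, base, tolerance = 1e-12)
})

test_that("medication change is after minus before", {
  expect_equal(medication_change(4.888, 3.447), -1.441)
  expect_equal(medication_change(5.720, 3.505), -2.215)
  expect_equal(medication_change(2.5, 2.5), 0)
})

test_that("cohort summaries use the sample SD convention", {
  mf <- pd_cohort_table("medication_frequency")
  s <- cohort_summary(mf$before_hz)
  expect_equal(s$mean, 2.012, tolerance = 0.005)
  expect_equal(s$sd, 1.385, tolerance = 0.005)
  expect_equal(cohort_summary(c(1, 2, 3)), list(mean = 2, sd = 1, n = 3L))
  expect_equal(cohort_summary(rep(7, 4))$sd, 0)
  expect_equal(cohort_summary(5)$sd, 0)
  expect_error(cohort_summary(NA_real_), "no values")
})

test_that("the comparison table implements complete-case analysis", {
  fr <- pd_cohort_table("frequency_validation")
  am <- pd_cohort_table("amplitude_validation")
  video <- data.frame(patient_id = fr$patient_id,
                      dominant_freq_hz = fr$f_vid_hz,
                      amplitude = am$a_vid_au)
  accel <- data.frame(patient_id = fr$patient_id[!is.na(fr$f_acc_hz)],
                      dominant_freq_hz = fr$f_acc_hz[!is.na(fr$f_acc_hz)],
                      amplitude = am$a_acc_cm_s2[!is.na(fr$f_acc_hz)])
  cmp <- build_comparison_table(video, accel)
  expect_identical(cmp$n, 10L)
  expect_identical(nrow(cmp$rows), 11L)  # PAT011 stays, with f_acc = NA
  expect_true(is.na(cmp$rows$f_acc[cmp$rows$patient_id == "PAT011"]))
  expect_equal(cmp$mean_ae, 0.229, tolerance = 0.005)
  expect_equal(cmp$sd_ae, 0.174, tolerance = 1e-3)
  expect_equal(cmp$rmse, 0.283, tolerance = 1e-3)
  expect_equal(round(cmp$pearson_r, 2), 0.98)

  # order independence
  perm <- sample(nrow(video))
  cmp2 <- build_comparison_table(video[perm, ], accel[sample(nrow(accel)), ])
  expect_equal(cmp2$mean_ae, cmp$mean_ae)
  expect_equal(cmp2$rows, cmp$rows)

  # rmse >= 0, and zero iff all pairs equal
  eq <- data.frame(patient_id = c("A", "B", "C"),
                   dominant_freq_hz = c(1, 2, 3))
  expect_gte(cmp$rmse, 0)
  expect_equal(build_comparison_table(eq, eq)$rmse, 0)

  # empty accelerometer set: n = 0, undefined RMSE flagged
  none <- data.frame(patient_id = character(0),
                     dominant_freq_hz = numeric(0))
  expect_warning(cmp0 <- build_comparison_table(video, none),
                 "no complete")
  expect_identical(cmp0$n, 0L)
  expect_true(is.na(cmp0$rmse))

  # duplicate patient ids are refused
  dup <- rbind(video, video[1, ])
  expect_error(build_comparison_table(dup, accel), "duplicate")
})

test_that("the medication table reproduces the benchmark cohort changes", {
  mf <- pd_cohort_table("medication_frequency")
  med <- build_medication_table(
    data.frame(patient_id = mf$patient_id, value = mf$before_hz),
    data.frame(patient_id = mf$patient_id, value = mf$after_hz))
  expect_identical(med$n, 10L)
  expect_equal(med$before_mean, 2.012, tolerance = 0.005)
  expect_equal(med$after_mean, 1.526, tolerance = 0.005)
  expect_equal(med$change_mean, -0.487, tolerance = 1e-3)
  expect_true(all(med$rows$change < 0))
  expect_equal(med$rows$change,
               medication_change(med$rows$before, med$rows$after))

  # identical sessions give zero change everywhere
  same <- data.frame(patient_id = mf$patient_id, value = mf$before_hz)
  med0 <- build_medication_table(same, same)
  expect_true(all(med0$rows$change == 0))
  expect_equal(med0$change_mean, 0)
})

test_that("report rounding is half away from zero", {
  expect_equal(round_half_up(1.0005, 3), 1.001)
  expect_equal(round_half_up(-1.0005, 3), -1.001)
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(0.2294, 3), 0.229)
})
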