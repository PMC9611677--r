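test_that("single-pass 3-SD rejection matches its definition", {
  # constant vector: SD = 0, nothing removed
  r <- reject_outliers(rep(1, 15))
  expect_equal(r$kept, rep(1, 15))
  expect_false(any(r$mask))

  # fourteen 1.0s and one 100: removed under both SD conventions
  v <- c(rep(1, 14), 100)
  for (mode in c("sample", "population")) {
    r <- reject_outliers(v, outlier_rule(3, mode))
    expect_equal(r$kept, rep(1, 14))
    expect_identical(which(r$mask), 15L)
  }

  # a single value is always kept
  r1 <- reject_outliers(4.2)
  expect_equal(r1$kept, 4.2)
  expect_false(r1$mask)
})

test_that("rejection agrees with a brute-force oracle on random vectors", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    v <- rnorm(n)
    if (runif(1) < 0.5) v[sample(n, 1)] <- rnorm(1, sd = 50)  # heavy outlier
    for (mode in c("sample", "population")) {
      m <- mean(v)
      s <- if (mode == "sample") sd(v) else sqrt(mean((v - m)^2))
      oracle <- logical(n)
      for (j in seq_len(n)) oracle[j] <- abs(v[j] - m) > 3 * s
      r <- reject_outliers(v, outlier_rule(3, mode))
      expect_identical(r$mask, oracle)
      expect_equal(r$kept, v[!oracle])
    }
  }
})

test_that("estimate_matrix fills a landmark-by-segment grid", {
  tone <- tone_signal(4, amp = 0.01, fs = 180, dur = 10,
                      units = "normalized_coordinate",
                      source = "video_landmark")
  signals <- lapply(0:20, function(i) { tone$landmark_id <- i; tone })
  mat <- estimate_matrix(signals)
  expect_identical(dim(mat$freq), c(21L, 5L))
  expect_identical(dim(mat$amp), c(21L, 5L))
  expect_true(all(abs(mat$freq - 4) <= mat$grid_hz))
  expect_true(all(mat$freq >= 0.5 & mat$freq <= 15))

  accel <- tone_signal(4, amp = 20, fs = 100, dur = 30,
                       units = "cm_per_s2", source = "accelerometer")
  m1 <- estimate_matrix(accel)
  expect_identical(dim(m1$freq), c(1L, 15L))
  expect_identical(m1$row_labels, "accel")

  short <- tone_signal(4, fs = 180, dur = 5)
  expect_error(estimate_matrix(list(tone, short)),
               "share sampling rate and length")
})

test_that("fusing identical estimates returns them unchanged", {
  mat <- structure(list(freq = matrix(4, 21, 5), amp = matrix(0.01, 21, 5),
                        row_labels = as.character(0:20), band = c(0.5, 15),
                        grid_hz = 0.05, n_segments = 5L),
                   class = "estimate_matrix")
  est <- fuse_estimates(mat)
  expect_equal(est$dominant_freq, 4)
  expect_equal(est$amplitude, 0.01)
  expect_identical(est$n_values_excluded, 0L)
  expect_identical(est$n_values_used, 105L)
})

test_that("an aberrant pseudo-noise row is excluded from the fusion", {
  set.seed(9)
  freq <- matrix(4 + rnorm(105, sd = 0.01), 21, 5)
  amp <- matrix(0.01, 21, 5)
  freq[13, ] <- c(0.9, 1.1, 0.7, 1.3, 0.8)  # one landmark gone rogue
  mat <- structure(list(freq = freq, amp = amp,
                        row_labels = as.character(0:20), band = c(0.5, 15),
                        grid_hz = 0.05, n_segments = 5L),
                   class = "estimate_matrix")
  est <- fuse_estimates(mat)
  expect_true(all(est$excluded_mask[13, ]))
  expect_false(any(est$excluded_mask[-13, ]))
  clean_mean <- mean(freq[-13, ])
  expect_lte(abs(est$dominant_freq - clean_mean), mat$grid_hz)
})

test_that("one aberrant accelerometer segment is rejected", {
  freq <- matrix(c(rep(4, 14), 14), 1, 15)
  amp <- matrix(c(rep(20, 14), 3), 1, 15)
  mat <- structure(list(freq = freq, amp = amp, row_labels = "accel",
                        band = c(0.5, 15), grid_hz = 0.05, n_segments = 15L),
                   class = "estimate_matrix")
  est <- fuse_estimates(mat)
  expect_identical(est$n_values_excluded, 1L)
  expect_equal(est$dominant_freq, 4)
  # the amplitude at the rejected position is excluded too (shared mask)
  expect_equal(est$amplitude, 20)
})

test_that("fusion is permutation-invariant and reduces to the mean", {
  set.seed(31)
  vals <- 4 + rnorm(105, sd = 0.2)
  amps <- runif(105, 0.005, 0.02)
  mk <- function(f, a) structure(
    list(freq = matrix(f, 21, 5), amp = matrix(a, 21, 5),
         row_labels = as.character(0:20), band = c(0.5, 15), grid_hz = 0.05,
         n_segments = 5L), class = "estimate_matrix")
  e1 <- fuse_estimates(mk(vals, amps))
  perm <- sample(105)
  e2 <- fuse_estimates(mk(vals[perm], amps[perm]))
  expect_equal(e1$dominant_freq, e2$dominant_freq)
  expect_equal(e1$amplitude, e2$amplitude)
  expect_identical(e1$n_values_excluded, e2$n_values_excluded)

  # with no value beyond 3 SD the fusion is the plain mean
  tight <- 4 + seq(-0.1, 0.1, length.out = 105)
  e3 <- fuse_estimates(mk(tight, amps))
  expect_identical(e3$n_values_excluded, 0L)
  expect_equal(e3$dominant_freq, mean(tight))
  expect_equal(e3$amplitude, mean(amps))
})

test_that("the estimator object supports the standard methods", {
  rec <- simulate_recording(sim_config(seed = 7))
  est <- estimate_tremor(rec)
  expect_s3_class(est, "tremor_estimate")
  co <- coef(est)
  expect_named(co, c("dominant_freq_hz", "amplitude"))
  expect_equal(unname(co["dominant_freq_hz"]), est$dominant_freq)
  expect_output(print(est), "dominant frequency")
  expect_output(print(summary(est)), "per-landmark")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(est))
  # bookkeeping invariant
  expect_identical(est$n_values_used + est$n_values_excluded,
                   length(est$matrix$freq))
  expect_length(est$per_landmark_freq, 21L)
})

test_that("per-landmark-mean pooling is available and consistent", {
  rec <- simulate_recording(sim_config(seed = 12))
  pooled <- estimate_tremor(rec)
  bymean <- estimate_tremor(rec, pooling = "per_landmark_mean")
  expect_lte(abs(pooled$dominant_freq - bymean$dominant_freq),
             2 * pooled$grid_hz)
})
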