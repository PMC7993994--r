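test_that("estimate_fmax summarizes the saturation plateau", {
  v <- c(runif(50, 0, 1), rep(5, 20))
  tr <- fluorescence_trace(v, window = c(1L, 50L))
  expect_equal(estimate_fmax(tr, c(51, 70), "median"), 5)
  expect_equal(estimate_fmax(tr, c(51, 70), "mean"), 5)
  expect_equal(estimate_fmax(tr, c(51, 70), "max"), 5)
  tr2 <- fluorescence_trace(c(rep(0.1, 10), 4, 5, 6), window = c(1L, 10L))
  expect_equal(estimate_fmax(tr2, c(11, 13), "median"), 5)
  expect_error(estimate_fmax(tr, c(60, 80)), "out-of-range")
  expect_error(estimate_fmax(tr, c(40, 60)), "after the analysis window")
})

test_that("plateau Fmax estimates recover the generator truth", {
  spec <- synthetic_spec(n_cells = 100, seed = 5)
  cohort <- simulate_cohort(spec)
  seg <- saturation_segment(spec)
  est <- vapply(cohort$traces, estimate_fmax, numeric(1), segment = seg)
  # plateau noise sd is 0.02 * fmax_raw over ~126 frames, so the median of
  # one plateau has sd ~0.0045; the cohort mean pins Fmax down tightly
  expect_lt(abs(mean(est) - spec$fmax_raw), 0.01)
  expect_true(all(abs(est - spec$fmax_raw) < 0.03))
})

test_that("normalization divides by Fmax and round-trips", {
  tr <- fluorescence_trace(c(1, 2, 4))
  n1 <- normalize_to_fmax(tr, 4)
  expect_equal(n1$values, c(0.25, 0.5, 1))
  expect_true(n1$normalized)
  expect_identical(n1$dt, tr$dt)
  expect_identical(n1$window, tr$window)
  tr_small <- fluorescence_trace(c(0.2, 0.5, 0.9))
  n2 <- normalize_to_fmax(tr_small, 1)
  expect_identical(n2$values, tr_small$values)
  expect_true(n2$normalized)
  expect_equal(n1$values * 4, tr$values, tolerance = 1e-15)
  expect_error(normalize_to_fmax(tr, 0), "fmax")
})

test_that("normalization is scale-equivariant", {
  set.seed(2)
  v <- runif(300, 0, 1.8)
  tr <- fluorescence_trace(v)
  for (c_ in c(0.01, 3, 250)) {
    scaled <- fluorescence_trace(c_ * v)
    expect_equal(normalize_to_fmax(scaled, c_ * 2)$values,
                 normalize_to_fmax(tr, 2)$values, tolerance = 1e-12)
  }
})

test_that("rolling-percentile baseline behaves on canonical shapes", {
  const <- fluorescence_trace(rep(0.7, 100))
  expect_equal(estimate_baseline(const), rep(0.7, 100))
  ramp <- fluorescence_trace(seq(0, 1, length.out = 200))
  b <- estimate_baseline(ramp)
  expect_true(all(diff(b) >= 0))
  expect_true(all(b <= cummax(ramp$values) + 1e-12))
  expect_error(estimate_baseline(const, window_frames = 101), "larger than trace")
  expect_error(estimate_baseline(const, percentile = 0), "percentile")
})

test_that("baseline tracks the resting level under sparse transients", {
  spec <- synthetic_spec(noise_sd = 0, drift_amplitude = 0,
                         baseline_level = 0.2, fmax_raw = 1, seed = 9)
  sim <- simulate_cell(spec, 1,
                       events = list(times_s = seq(40, 440, by = 50),
                                     amplitudes = 0.5))
  b <- estimate_baseline(sim$trace, window_frames = 21, percentile = 20)
  in_window <- seq_len(sim$trace$window[2])
  frac_close <- mean(abs(b[in_window] - 0.2) < 0.01)
  expect_gte(frac_close, 0.95)
})

test_that("absolute calcium calibration is exact at its anchor points", {
  calib <- calibration_params(0.1, 1.0, 345)
  expect_equal(absolute_calcium(0.1, calib), 0)
  expect_equal(absolute_calcium(0.55, calib), 345)
  expect_error(absolute_calcium(1.0, calib), "saturated")
  expect_error(absolute_calcium(0.05, calib), "below Fmin")
})

test_that("calibration is monotone and diverges toward Fmax", {
  set.seed(31)
  for (i in 1:25) {
    f_min <- runif(1, 0, 0.5)
    f_max <- f_min + runif(1, 0.2, 2)
    kd <- runif(1, 100, 1000)
    calib <- calibration_params(f_min, f_max, kd)
    f <- sort(runif(50, f_min, f_max - 1e-6))
    ca <- absolute_calcium(f, calib)
    expect_true(all(diff(ca) > 0))
  }
  calib <- calibration_params(0.1, 1.0, 345)
  eps <- 10^seq(-2, -8, by = -1)
  ca <- absolute_calcium(1.0 - eps, calib)
  expect_equal(ca, 345 * (0.9 - eps) / eps, tolerance = 1e-6)
  expect_true(all(diff(ca) > 0))  # grows without bound as eps shrinks
})
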