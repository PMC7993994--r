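test_that("the frame rule matches hand-evaluated cases", {
  p <- detection_params(3, 7, 0.25)
  # lone spike: local max holds; local mean 1/15, threshold 1.25/15 < 1
  v <- rep(0, 20); v[10] <- 1
  expect_true(is_transient_frame(v, 10, p))
  expect_false(is_transient_frame(v, 12, p))
  # constant positive trace: condition (ii) demands c > (1+gamma)*c
  expect_false(any(vapply(8:13, function(n) {
    is_transient_frame(rep(0.4, 20), n, p)
  }, logical(1))))
  # two-frame plateau: >= makes both frames qualify individually
  v2 <- rep(0, 20); v2[9:10] <- 1
  expect_true(is_transient_frame(v2, 9, p))
  expect_true(is_transient_frame(v2, 10, p))
  expect_error(is_transient_frame(v, 5, p), "incomplete window")
})

test_that("plateau ties merge to a single event at the earliest top frame", {
  v2 <- rep(0, 20); v2[9:10] <- 1
  tr <- fluorescence_trace(v2, normalized = TRUE)
  res <- suppressMessages(detect_transients(tr, detection_params(3, 7, 0.25)))
  expect_equal(res$events$peak_frame, 9L)
})

test_that("degenerate traces yield no events", {
  dec <- fluorescence_trace(seq(1, 0.01, length.out = 60), normalized = TRUE)
  expect_equal(nrow(suppressMessages(detect_transients(dec))$events), 0L)
  expect_error(suppressMessages(detect_transients(
    fluorescence_trace(runif(10), normalized = TRUE))), "too short")
})

test_that("planted well-separated transients are all recovered near truth", {
  spec <- synthetic_spec(drift_amplitude = 0, seed = 21)
  times <- seq(30, 380, by = 50)  # 8 events, amplitude 15x noise sd
  sim <- simulate_cell(spec, 1, events = list(times_s = times, amplitudes = 0.3))
  tr <- normalize_to_fmax(sim$trace, estimate_fmax(sim$trace, saturation_segment(spec)))
  res <- detect_transients(tr)
  matched <- vapply(sim$truth$event_frames, function(f) {
    any(abs(res$events$peak_frame - f) <= 3)
  }, logical(1))
  expect_true(all(matched))
})

test_that("vectorized detection equals the brute-force rule on random traces", {
  set.seed(77)
  for (case in 1:200) {
    len <- sample(60:400, 1)
    p <- detection_params(sample(1:5, 1), sample(3:10, 1), runif(1, 0.1, 1))
    v <- if (case %% 2 == 0) {
      runif(len)
    } else {
      base <- rep(0.1, len)
      base[sample(len, 8)] <- runif(8, 0.3, 1)
      base + rnorm(len, 0, 0.01)^2
    }
    a <- sample.int(len %/% 4, 1)
    b <- len - sample.int(len %/% 4, 1)
    tr <- fluorescence_trace(v, window = c(a, b), normalized = TRUE)
    got <- detect_transients(tr, p)$events$peak_frame
    want <- brute_detect(v, c(a, b), p$delta, p$theta, p$gamma, p$merge_gap)
    expect_identical(got, as.integer(want))
  }
})

test_that("detection is scale-invariant but not offset-invariant", {
  spec <- synthetic_spec(seed = 13)
  sim <- simulate_cell(spec, 2)
  v <- sim$trace$values
  base_peaks <- suppressMessages(
    detect_transients(fluorescence_trace(v))
  )$events$peak_frame
  expect_gt(length(base_peaks), 0)
  for (c_ in c(0.01, 7, 1000)) {
    peaks <- suppressMessages(
      detect_transients(fluorescence_trace(c_ * v))
    )$events$peak_frame
    expect_identical(peaks, base_peaks)
  }
  # a large additive offset inflates the local mean and kills detections
  shifted <- suppressMessages(
    detect_transients(fluorescence_trace(v + 50))
  )$events$peak_frame
  expect_length(shifted, 0)
})

test_that("raising gamma only removes qualifying frames", {
  spec <- synthetic_spec(seed = 17)
  sim <- simulate_cell(spec, 1)
  v <- sim$trace$values
  m <- 7
  eligible <- (1 + m):(sim$trace$window[2] - m)
  qual_at <- function(gamma) {
    p <- detection_params(3, 7, gamma)
    eligible[vapply(eligible, function(n) is_transient_frame(v, n, p), logical(1))]
  }
  q1 <- qual_at(0.25); q2 <- qual_at(0.6); q3 <- qual_at(5)
  expect_true(all(q2 %in% q1))
  expect_true(all(q3 %in% q2))
})

test_that("clearance time matches closed forms on noiseless decays", {
  # exponential: time from peak to half amplitude is tau * ln 2
  for (tau in c(0.5, 1.0, 1.5, 3.0)) {
    dt <- 0.478
    tt <- seq(0, 30, by = dt)
    v <- exp(-tt / tau)
    tr <- fluorescence_trace(v, dt = dt, normalized = TRUE)
    got <- clearance_time(tr, list(peak_frame = 1L, baseline = 0, amplitude = 1))
    expect_lte(abs(got - tau * log(2)), dt)
  }
  # fine sampling pins it down
  dt <- 0.01
  v <- exp(-seq(0, 10, by = dt) / 1.5)
  tr <- fluorescence_trace(v, dt = dt, normalized = TRUE)
  got <- clearance_time(tr, list(peak_frame = 1L, baseline = 0, amplitude = 1))
  expect_lte(abs(got - 1.5 * log(2)), dt)
  # linear decay from A to 0 over D seconds crosses A/2 at D/2
  D <- 10; dt <- 0.478
  v <- pmax(1 - seq(0, 15, by = dt) / D, 0)
  tr <- fluorescence_trace(v, dt = dt, normalized = TRUE)
  got <- clearance_time(tr, list(peak_frame = 1L, baseline = 0, amplitude = 1))
  expect_lte(abs(got - D / 2), dt)
})

test_that("clearance is missing when truncation precedes the half crossing", {
  v <- c(rep(0.1, 10), 1, 0.95, 0.9)
  tr <- fluorescence_trace(v, normalized = TRUE)
  ev <- list(peak_frame = 11L, baseline = 0.1, amplitude = 0.9)
  expect_true(is.na(clearance_time(tr, ev)))                     # window ends first
  expect_true(is.na(clearance_time(tr, ev, truncate_frame = 12)))  # next peak first
  # no samples after the peak at all
  tr2 <- fluorescence_trace(c(rep(0.1, 10), 1), normalized = TRUE)
  expect_true(is.na(clearance_time(tr2, list(peak_frame = 11L, baseline = 0.1,
                                             amplitude = 0.9))))
})

test_that("per-cell summaries follow the mean-over-transients definitions", {
  const <- fluorescence_trace(rep(0.3, 120), cell_id = "c", normalized = TRUE)
  empty <- fake_result("c", data.frame(peak_frame = integer(0),
                                       peak_time_s = numeric(0),
                                       peak_value = numeric(0),
                                       baseline = numeric(0),
                                       amplitude = numeric(0),
                                       half_decay_s = numeric(0)),
                       c(1L, 120L))
  m <- summarize_cell(empty, const)
  expect_equal(m$n_transients, 0L)
  expect_equal(m$firing_rate_per_min, 0)
  expect_true(is.na(m$clearance_time_s) && is.na(m$amplitude))
  expect_equal(m$mean_signal, 0.3)

  two <- fake_result("c", data.frame(peak_frame = c(20L, 60L),
                                     peak_time_s = c(19, 59) * 0.478,
                                     peak_value = c(0.5, 0.7),
                                     baseline = c(0.3, 0.3),
                                     amplitude = c(0.2, 0.4),
                                     half_decay_s = c(1.0, 2.0)),
                     c(1L, 120L))
  m2 <- summarize_cell(two, const)
  expect_equal(m2$clearance_time_s, 1.5)
  expect_equal(m2$amplitude, 0.3)
  expect_equal(m2$firing_rate_per_min, 2 / (120 * 0.478 / 60))
  # a truncated half-decay drops out of T but not out of A
  two$events$half_decay_s[2] <- NA
  m3 <- summarize_cell(two, const)
  expect_equal(m3$clearance_time_s, 1.0)
  expect_equal(m3$amplitude, 0.3)
  expect_error(summarize_cell(two, fluorescence_trace(rep(0.3, 120), cell_id = "other")),
               "cell_id mismatch")
})

test_that("group comparison handles symmetry, separation and missingness", {
  a <- data.frame(clearance_time_s = c(1, 2, 3, 4))
  expect_equal(compare_groups(a, a, "clearance_time_s")$statistic, 0)
  expect_equal(compare_groups(a, a, "clearance_time_s")$p_value, 1)

  set.seed(4)
  lo <- data.frame(amplitude = rnorm(4, 0, 1e-6))
  hi <- data.frame(amplitude = 1 + rnorm(4, 0, 1e-6))
  expect_lt(compare_groups(lo, hi, "amplitude")$p_value, 1e-6)

  with_na <- data.frame(amplitude = c(1, 2, NA, 3))
  cmp <- compare_groups(with_na, hi, "amplitude")
  expect_equal(cmp$n_a, 3)
  expect_equal(cmp$n_missing_a, 1)
  expect_error(compare_groups(data.frame(amplitude = c(1, NA, NA)), hi, "amplitude"),
               "insufficient non-missing")
  expect_match(compare_groups(lo, hi, "amplitude", var_equal = TRUE)$method,
               "Two Sample t-test")
})
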