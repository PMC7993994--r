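# Independent oracles, written as plain loops so they share no code path
# with the package implementation.

# Frame-by-frame evaluation of the detection rule plus merging.
brute_detect <- function(values, window, delta, theta, gamma, merge_gap) {
  m <- max(delta, theta)
  lo <- max(window[1] + m, 1 + m)
  hi <- min(window[2] - m, length(values) - m)
  qual <- integer(0)
  if (lo <= hi) {
    for (n in lo:hi) {
      cond1 <- TRUE
      for (a in (n - delta):(n + delta)) {
        if (values[n] < values[a]) { cond1 <- FALSE; break }
      }
      if (!cond1) next
      s <- 0
      for (j in (n - theta):(n + theta)) s <- s + values[j]
      if (values[n] > (1 + gamma) / (2 * theta + 1) * s) qual <- c(qual, n)
    }
  }
  # merge runs of qualifying frames separated by <= merge_gap
  peaks <- integer(0)
  i <- 1L
  while (i <= length(qual)) {
    j <- i
    while (j < length(qual) && qual[j + 1L] - qual[j] <= merge_gap) j <- j + 1L
    run <- qual[i:j]
    best <- run[1L]
    for (q in run) if (values[q] > values[best]) best <- q
    peaks <- c(peaks, best)
    i <- j + 1L
  }
  peaks
}

# Monte-Carlo expectation of the event count for a Poisson process with a
# hard (non-paralyzable) refractory gap over a finite window.
thinned_count_oracle <- function(lambda_s, refractory_s, duration_s, n_windows = 500L) {
  counts <- numeric(n_windows)
  for (w in seq_len(n_windows)) {
    t <- 0; last <- -Inf; k <- 0L
    repeat {
      t <- t + stats::rexp(1, lambda_s)
      if (t >= duration_s) break
      if (t - last >= refractory_s) { k <- k + 1L; last <- t }
    }
    counts[w] <- k
  }
  list(mean = mean(counts), se = stats::sd(counts) / sqrt(n_windows))
}

# A trace with spikes planted at known frames on a flat baseline.
planted_trace <- function(n_frames, spike_frames, amplitude = 1, baseline = 0,
                          dt = 0.478) {
  v <- rep(baseline, n_frames)
  v[spike_frames] <- baseline + amplitude
  fluorescence_trace(v, cell_id = "planted", dt = dt, normalized = FALSE)
}

# Minimal detection_result for exercising summarize_cell directly.
fake_result <- function(cell_id, events, window, params = detection_params()) {
  structure(list(cell_id = cell_id, events = events, params = params,
                 window = as.integer(window)),
            class = "detection_result")
}
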