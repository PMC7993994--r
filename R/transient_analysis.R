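#' Test the transient rule at a single frame
#'
#' A frame n qualifies as a transient peak when both conditions of the
#' windowed rule hold: (i) F(n) is a local maximum, `F(n) >= F(a)` for every
#' a in `[n - delta, n + delta]`, and (ii) F(n) exceeds the local mean by
#' the relative margin gamma,
#' `F(n) > (1 + gamma) / (2 theta + 1) * sum(F[n - theta .. n + theta])`.
#' The result is a pure function of the `2 * max(delta, theta) + 1`
#' surrounding values; frames without a complete surrounding window are not
#' testable.
#'
#' @param trace A [fluorescence_trace()] or numeric vector.
#' @param n Frame index (1-based).
#' @param params A [detection_params()].
#' @return Logical scalar.
#' @export
is_transient_frame <- function(trace, n, params) {
  v <- if (inherits(trace, "fluorescence_trace")) trace$values else as.numeric(trace)
  if (!inherits(params, "detection_params")) stop("params must be detection_params", call. = FALSE)
  n <- as.integer(n)
  m <- max(params$delta, params$theta)
  if (n - m < 1L || n + m > length(v)) {
    stop(sprintf("incomplete window: frame %d needs %d frames on each side", n, m),
         call. = FALSE)
  }
  local_max <- v[n] >= max(v[(n - params$delta):(n + params$delta)])
  s <- sum(v[(n - params$theta):(n + params$theta)])
  above_mean <- v[n] > (1 + params$gamma) / (2 * params$theta + 1) * s
  local_max && above_mean
}

#' Detect calcium transients in a trace
#'
#' Applies the windowed detection rule (see [is_transient_frame()]) to every
#' frame of the analysis window that has a complete surrounding window of
#' `max(delta, theta)` frames, then collapses runs of qualifying frames
#' separated by at most `merge_gap` frames into single events. Flat-topped
#' transients qualify at several tied frames because the local-maximum
#' condition uses `>=`; each merged run is represented by its highest-F
#' frame (earliest frame on exact ties). Every event is annotated with the
#' rolling-percentile baseline at its peak, the amplitude above that
#' baseline, and the half-amplitude clearance time.
#'
#' The rule is invariant under positive rescaling of the trace (both
#' conditions are homogeneous in F), so detection gives identical peaks on
#' raw and Fmax-normalized values; additive offsets are not neutral (they
#' inflate the local mean and suppress detections), which is why
#' normalization rather than background subtraction precedes detection.
#'
#' @param trace A [fluorescence_trace()], normalized or raw. A message is
#'   emitted for raw traces.
#' @param params A [detection_params()].
#' @param baseline_window,baseline_percentile Passed to
#'   [estimate_baseline()].
#' @return An object of class `detection_result`: list with `cell_id`,
#'   `events` (data frame with columns `peak_frame`, `peak_time_s`,
#'   `peak_value`, `baseline`, `amplitude`, `half_decay_s`), `params`,
#'   `window`.
#' @export
detect_transients <- function(trace, params = detection_params(),
                              baseline_window = 21L,
                              baseline_percentile = 20) {
  validate_trace(trace)
  if (!inherits(params, "detection_params")) stop("params must be detection_params", call. = FALSE)
  v <- trace$values
  m <- max(params$delta, params$theta)
  if (length(v) <= 2L * m) {
    stop(sprintf("trace too short: need more than %d frames for delta=%d, theta=%d",
                 2L * m, params$delta, params$theta), call. = FALSE)
  }
  if (!trace$normalized) {
    message(sprintf("cell %s: detecting on a raw (non-normalized) trace", trace$cell_id))
  }

  a <- trace$window[1L]; b <- trace$window[2L]
  lo <- max(a + m, 1L + m)
  hi <- min(b - m, length(v) - m)

  qual <- integer(0)
  if (lo <= hi) {
    n_seq <- lo:hi
    # local max over +/- delta: rollmax is centered on positions (delta+1)..(len-delta)
    if (params$delta > 0L) {
      rmax <- zoo::rollmax(v, 2L * params$delta + 1L, align = "center")
      cond1 <- v[n_seq] >= rmax[n_seq - params$delta]
    } else {
      cond1 <- rep(TRUE, length(n_seq))
    }
    rsum <- zoo::rollsum(v, 2L * params$theta + 1L, align = "center")
    thr <- (1 + params$gamma) / (2 * params$theta + 1)
    cond2 <- v[n_seq] > thr * rsum[n_seq - params$theta]
    qual <- n_seq[cond1 & cond2]
  }

  peaks <- merge_qualifying_frames(qual, v, params$merge_gap)

  # rolling-percentile baseline, evaluated only where it is needed
  base_at_peaks <- pmin(
    rolling_percentile(v, peaks, as.integer(baseline_window),
                       baseline_percentile / 100),
    cummax(v)[peaks]
  )
  k <- length(peaks)
  events <- data.frame(
    peak_frame = as.integer(peaks),
    peak_time_s = (peaks - 1) * trace$dt,
    peak_value = v[peaks],
    baseline = base_at_peaks,
    amplitude = pmax(0, v[peaks] - base_at_peaks),
    half_decay_s = rep(NA_real_, k),
    stringsAsFactors = FALSE
  )
  if (k > 0L) {
    next_peak <- c(events$peak_frame[-1L], NA_integer_)
    for (i in seq_len(k)) {
      trunc_at <- if (is.na(next_peak[i])) b else min(next_peak[i], b)
      events$half_decay_s[i] <- clearance_time(
        trace,
        list(peak_frame = events$peak_frame[i],
             baseline = events$baseline[i],
             amplitude = events$amplitude[i]),
        truncate_frame = trunc_at
      )
    }
  }

  structure(list(cell_id = trace$cell_id, events = events, params = params,
                 window = trace$window),
            class = "detection_result")
}

# Collapse runs of qualifying frames separated by <= merge_gap into single
# events at the highest-F frame (earliest on exact ties).
merge_qualifying_frames <- function(qual, values, merge_gap) {
  if (length(qual) == 0L) return(integer(0))
  grp <- cumsum(c(1L, as.integer(diff(qual) > merge_gap)))
  vapply(split(qual, grp),
         function(q) q[which.max(values[q])],
         integer(1), USE.NAMES = FALSE)
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> cell %s: %d events in window [%d, %d]\n",
              x$cell_id, nrow(x$events), x$window[1L], x$window[2L]))
  invisible(x)
}

#' Half-amplitude clearance time of a transient
#'
#' Time from the transient's peak to the first subsequent instant at which
#' the signal falls to `baseline + amplitude / 2` ("from maximum to half of
#' the amplitude"), located by linear interpolation between the bracketing
#' frames. The search stops at `truncate_frame` (typically the next event's
#' peak, or the analysis-window end); if the half-amplitude level is not
#' reached before truncation the value is missing (`NA`), never a truncated
#' time — a truncated time would bias mean clearance downward at high
#' firing rates.
#'
#' For an exponential decay with time constant tau the returned time is
#' `tau * log(2)` up to discretization.
#'
#' @param trace The [fluorescence_trace()] the event was detected on.
#' @param event List or one-row data frame with `peak_frame`, `baseline`,
#'   `amplitude`.
#' @param truncate_frame Last frame (inclusive) searched for the crossing;
#'   defaults to the analysis-window end.
#' @return Clearance time in seconds, or `NA_real_`.
#' @export
clearance_time <- function(trace, event, truncate_frame = trace$window[2L]) {
  v <- trace$values
  p <- as.integer(event$peak_frame)
  amp <- as.numeric(event$amplitude)
  if (!is.finite(amp) || amp <= 0) return(NA_real_)
  level <- as.numeric(event$baseline) + amp / 2
  trunc_at <- min(as.integer(truncate_frame), length(v))
  if (p >= trunc_at) return(NA_real_)
  seg <- (p + 1L):trunc_at
  below <- which(v[seg] <= level)
  if (length(below) == 0L) return(NA_real_)
  k <- seg[below[1L]]
  # v[k - 1] > level >= v[k]; interpolate the crossing linearly
  frac <- (v[k - 1L] - level) / (v[k - 1L] - v[k])
  ((k - 1L - p) + frac) * trace$dt
}

#' Summarize a cell's detected transients
#'
#' Computes the four per-cell statistics: transient count N, firing rate
#' (transients per minute over the analysis window), mean clearance time T
#' over transients with a defined half-decay, mean amplitude A, and the
#' mean signal over the window. Cells without qualifying transients get
#' missing T and A (never zero, which would contaminate group means).
#'
#' @param result A `detection_result` from [detect_transients()].
#' @param trace The matching [fluorescence_trace()].
#' @return One-row data frame with columns `cell_id`, `n_transients`,
#'   `firing_rate_per_min`, `clearance_time_s`, `amplitude`, `mean_signal`.
#' @export
summarize_cell <- function(result, trace) {
  if (!inherits(result, "detection_result")) stop("result must be a detection_result", call. = FALSE)
  validate_trace(trace)
  if (!identical(result$cell_id, trace$cell_id)) {
    stop(sprintf("cell_id mismatch: result '%s' vs trace '%s'",
                 result$cell_id, trace$cell_id), call. = FALSE)
  }
  ev <- result$events
  n <- nrow(ev)
  dur_min <- window_duration_s(trace$window, trace$dt) / 60
  decays <- ev$half_decay_s[!is.na(ev$half_decay_s)]
  data.frame(
    cell_id = trace$cell_id,
    n_transients = n,
    firing_rate_per_min = n / dur_min,
    clearance_time_s = if (length(decays) > 0L) mean(decays) else NA_real_,
    amplitude = if (n > 0L) mean(ev$amplitude) else NA_real_,
    mean_signal = mean(trace$values[trace$window[1L]:trace$window[2L]]),
    stringsAsFactors = FALSE
  )
}

#' Compare a per-cell metric between two groups
#'
#' Two-sample unpaired two-tailed t-test on per-cell values of one metric.
#' Welch's unequal-variance form is the default; the classic pooled-variance
#' Student form is available with `var_equal = TRUE`. Missing values (cells
#' without qualifying transients) are excluded, with counts reported.
#'
#' @param metrics_a,metrics_b Data frames of per-cell metrics, as returned
#'   by [summarize_cell()] (row-bound across cells).
#' @param field Metric column to compare, e.g. `"clearance_time_s"`,
#'   `"amplitude"`, `"mean_signal"`, `"firing_rate_per_min"`.
#' @param var_equal Use the pooled-variance Student t-test instead of
#'   Welch's.
#' @return List with `field`, `statistic` (t), `df`, `p_value`, `mean_a`,
#'   `mean_b`, `sem_a`, `sem_b`, `n_a`, `n_b`, `n_missing_a`,
#'   `n_missing_b`, `method`.
#' @export
compare_groups <- function(metrics_a, metrics_b, field, var_equal = FALSE) {
  for (df_ in list(metrics_a, metrics_b)) {
    if (!field %in% names(df_)) stop(sprintf("no metric column '%s'", field), call. = FALSE)
  }
  xa <- metrics_a[[field]]; xb <- metrics_b[[field]]
  miss_a <- sum(is.na(xa)); miss_b <- sum(is.na(xb))
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (length(xa) < 2L || length(xb) < 2L) {
    stop(sprintf("insufficient non-missing data for '%s': %d vs %d values",
                 field, length(xa), length(xb)), call. = FALSE)
  }
  tt <- stats::t.test(xa, xb, alternative = "two.sided", var.equal = var_equal)
  list(
    field = field,
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(xa), mean_b = mean(xb),
    sem_a = stats::sd(xa) / sqrt(length(xa)),
    sem_b = stats::sd(xb) / sqrt(length(xb)),
    n_a = length(xa), n_b = length(xb),
    n_missing_a = miss_a, n_missing_b = miss_b,
    method = tt$method
  )
}
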