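#' Specification for synthetic calcium traces
#'
#' Generative parameters for traces that emulate spontaneously active
#' cortical neurons imaged at 478 ms frames: sparse calcium transients with
#' a fast linear rise and exponential decay, riding on a slowly drifting
#' baseline with additive Gaussian noise, followed (optionally) by an
#' ionomycin saturation segment that ramps to and holds the Fmax plateau.
#' Event times are a Poisson process thinned by a hard refractory gap.
#' Amplitudes are lognormal in normalized (F/Fmax) units; the raw trace is
#' the normalized signal scaled by `fmax_raw`.
#'
#' @param n_cells Number of cells in the cohort.
#' @param duration_s Length of the spontaneous-activity analysis window in
#'   seconds (default 478).
#' @param dt Frame interval in seconds (default 0.478).
#' @param event_rate_per_min Rate of the underlying Poisson event process,
#'   per minute, before refractory thinning (default 6).
#' @param refractory_s Hard minimum gap between events in seconds (default
#'   3).
#' @param edge_margin_s Events are confined to
#'   `[edge_margin_s, duration_s - edge_margin_s]` so every transient is
#'   fully contained in the analysis window — its peak observable with
#'   surrounding context and its decay recorded (default 5).
#' @param amplitude_mean,amplitude_cv Mean and coefficient of variation of
#'   lognormal event amplitudes in normalized units (defaults 0.3, 0.25).
#' @param tau_s Exponential decay constant in seconds (default 1.5).
#' @param rise_frames Frames of linear rise to the peak (default 1).
#' @param baseline_level Resting level in normalized units (default 0.15).
#' @param noise_sd Additive Gaussian noise sd in normalized units (default
#'   0.02).
#' @param drift_amplitude Amplitude of a slow sinusoidal baseline drift in
#'   normalized units (default 0.01).
#' @param drift_period_s Period of the drift in seconds (default 120).
#' @param ionomycin Append a saturation segment after the analysis window
#'   (default `TRUE`).
#' @param ionomycin_ramp_s,ionomycin_plateau_s Duration of the saturation
#'   onset ramp and of the plateau held at Fmax (defaults 20 and 60 s; the
#'   plateau is kept short relative to a real recording because only its
#'   summary statistic matters).
#' @param fmax_raw Raw-unit scale factor: the true Fmax of the raw trace
#'   (default 2).
#' @param fmin_frac True fluorescence floor (zero-calcium/BAPTA condition)
#'   as a fraction of `fmax_raw`; recorded in the ground truth for
#'   calibration checks, not simulated as a trace segment (default 0.05).
#' @param seed Integer seed; the full cohort is a pure function of the
#'   spec, seed included.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 50L, duration_s = 478, dt = 0.478,
                           event_rate_per_min = 6, refractory_s = 3,
                           edge_margin_s = 5,
                           amplitude_mean = 0.3, amplitude_cv = 0.25,
                           tau_s = 1.5, rise_frames = 1L,
                           baseline_level = 0.15, noise_sd = 0.02,
                           drift_amplitude = 0.01, drift_period_s = 120,
                           ionomycin = TRUE,
                           ionomycin_ramp_s = 20, ionomycin_plateau_s = 60,
                           fmax_raw = 2.0, fmin_frac = 0.05, seed = 1L) {
  spec <- list(n_cells = as.integer(n_cells), duration_s = duration_s, dt = dt,
               event_rate_per_min = event_rate_per_min,
               refractory_s = refractory_s,
               edge_margin_s = edge_margin_s,
               amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
               tau_s = tau_s, rise_frames = as.integer(rise_frames),
               baseline_level = baseline_level, noise_sd = noise_sd,
               drift_amplitude = drift_amplitude,
               drift_period_s = drift_period_s,
               ionomycin = isTRUE(ionomycin),
               ionomycin_ramp_s = ionomycin_ramp_s,
               ionomycin_plateau_s = ionomycin_plateau_s,
               fmax_raw = fmax_raw, fmin_frac = fmin_frac,
               seed = as.integer(seed))
  with(spec, {
    if (n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
    if (dt <= 0) stop("dt must be > 0", call. = FALSE)
    if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
    if (edge_margin_s < 0 || 2 * edge_margin_s >= duration_s) {
      stop("edge_margin_s must be >= 0 and leave a non-empty event interval",
           call. = FALSE)
    }
    if (event_rate_per_min < 0 || refractory_s < 0 || amplitude_mean < 0 ||
        amplitude_cv < 0 || noise_sd < 0 || drift_amplitude < 0 ||
        baseline_level < 0) {
      stop("rates, scales and sds must be non-negative", call. = FALSE)
    }
    if (tau_s <= 0) stop("tau_s must be > 0", call. = FALSE)
    if (rise_frames < 1L) stop("rise_frames must be >= 1", call. = FALSE)
    if (fmax_raw <= 0) stop("fmax_raw must be > 0", call. = FALSE)
    if (fmin_frac < 0 || fmin_frac >= 1) stop("fmin_frac must be in [0, 1)", call. = FALSE)
  })
  structure(spec, class = "synthetic_spec")
}

# Deterministic per-cell RNG seed below 2^31.
cell_seed <- function(seed, cell_index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(cell_index) * 104729) %% 2147483647)
}

#' Simulate one cell's trace with ground truth
#'
#' Draws event times from a Poisson process thinned by the refractory rule,
#' assigns lognormal amplitudes, composes the trace as
#' `fmax_raw * clip(baseline + drift + sum of kernels + noise, 0)`, and, if
#' `ionomycin` is set, appends the saturation ramp and plateau after the
#' analysis window. Each kernel rises linearly over `rise_frames` frames
#' and decays as `exp(-t / tau_s)`. Deterministic given `(spec$seed,
#' cell_index)`; sets the global RNG state.
#'
#' @param spec A [synthetic_spec()].
#' @param cell_index Positive integer identifying the cell.
#' @param events Optional list with `times_s` (event onset times in
#'   seconds) and `amplitudes` (normalized units) overriding the random
#'   event draw — useful for constructing traces with known transients.
#' @return List with `trace` (a [fluorescence_trace()], raw units) and
#'   `truth` (list: `cell_id`, `event_times_s` and `event_frames` at the
#'   transient peaks, `amplitudes` in normalized units, `tau_s`,
#'   `baseline` series over the analysis window in normalized units,
#'   `fmax`, `fmin`).
#' @export
simulate_cell <- function(spec, cell_index, events = NULL) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec", call. = FALSE)
  cell_index <- as.integer(cell_index)
  if (is.na(cell_index) || cell_index < 1L) stop("cell_index must be >= 1", call. = FALSE)
  set.seed(cell_seed(spec$seed, cell_index))

  n_win <- as.integer(round(spec$duration_s / spec$dt))
  t_frames <- (seq_len(n_win) - 1) * spec$dt
  rise_s <- spec$rise_frames * spec$dt

  # Poisson onsets thinned by the hard refractory gap; truth records peaks.
  lambda_s <- spec$event_rate_per_min / 60
  onsets <- numeric(0)
  if (!is.null(events)) {
    onsets <- as.numeric(events$times_s)
  } else if (lambda_s > 0) {
    # Poisson process confined to the interior so transients are fully
    # observable; peaks land in [edge_margin_s, duration_s - edge_margin_s]
    t_lo <- spec$edge_margin_s
    t_hi <- spec$duration_s - spec$edge_margin_s - rise_s
    cand <- t_lo + cumsum(stats::rexp(ceiling(4 * lambda_s * spec$duration_s) + 20,
                                      rate = lambda_s))
    cand <- cand[cand < t_hi]
    keep <- logical(length(cand))
    last <- -Inf
    for (i in seq_along(cand)) {
      if (cand[i] - last >= spec$refractory_s) {
        keep[i] <- TRUE
        last <- cand[i]
      }
    }
    onsets <- cand[keep]
  }
  k <- length(onsets)
  if (!is.null(events)) {
    amps <- rep_len(as.numeric(events$amplitudes), k)
  } else if (spec$amplitude_cv > 0) {
    sdlog <- sqrt(log(1 + spec$amplitude_cv^2))
    meanlog <- log(spec$amplitude_mean) - sdlog^2 / 2
    amps <- stats::rlnorm(k, meanlog, sdlog)
  } else {
    amps <- rep(spec$amplitude_mean, k)
  }

  phase <- stats::runif(1, 0, 2 * pi)
  drift <- spec$drift_amplitude * sin(2 * pi * t_frames / spec$drift_period_s + phase)
  base_win <- spec$baseline_level + drift

  signal <- base_win
  for (i in seq_len(k)) {
    s <- t_frames - onsets[i]
    active <- which(s > 0 & s < rise_s + 12 * spec$tau_s)
    si <- s[active]
    kern <- ifelse(si <= rise_s,
                   amps[i] * si / rise_s,
                   amps[i] * exp(-(si - rise_s) / spec$tau_s))
    signal[active] <- signal[active] + kern
  }

  if (spec$ionomycin) {
    n_ramp <- max(1L, as.integer(round(spec$ionomycin_ramp_s / spec$dt)))
    n_plat <- max(1L, as.integer(round(spec$ionomycin_plateau_s / spec$dt)))
    ramp <- seq(spec$baseline_level, 1, length.out = n_ramp + 1L)[-1L]
    signal <- c(signal, ramp, rep(1, n_plat))
  }

  noise <- stats::rnorm(length(signal), 0, spec$noise_sd)
  values <- spec$fmax_raw * pmax(signal + noise, 0)

  cell_id <- sprintf("cell_%03d", cell_index)
  trace <- fluorescence_trace(values, cell_id = cell_id, dt = spec$dt,
                              window = c(1L, n_win), normalized = FALSE)
  peak_times <- onsets + rise_s
  truth <- list(
    cell_id = cell_id,
    event_times_s = peak_times,
    event_frames = as.integer(round(peak_times / spec$dt)) + 1L,
    amplitudes = amps,
    tau_s = spec$tau_s,
    baseline = base_win,
    fmax = spec$fmax_raw,
    fmin = spec$fmax_raw * spec$fmin_frac
  )
  list(trace = trace, truth = truth)
}

#' Simulate a cohort of cells
#'
#' @param spec A [synthetic_spec()].
#' @return List with `traces` (list of [fluorescence_trace()]) and `truth`
#'   (list of per-cell ground-truth lists), both of length `spec$n_cells`.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec", call. = FALSE)
  cells <- lapply(seq_len(spec$n_cells), function(i) simulate_cell(spec, i))
  list(traces = lapply(cells, `[[`, "trace"),
       truth = lapply(cells, `[[`, "truth"))
}

#' Saturation segment of a simulated trace
#'
#' Frame range of the ionomycin plateau (excluding the onset ramp) implied
#' by a spec, for use with [estimate_fmax()].
#'
#' @param spec A [synthetic_spec()] with `ionomycin = TRUE`.
#' @return Integer pair `c(start, end)`.
#' @export
saturation_segment <- function(spec) {
  if (!isTRUE(spec$ionomycin)) stop("spec has no ionomycin segment", call. = FALSE)
  n_win <- as.integer(round(spec$duration_s / spec$dt))
  n_ramp <- max(1L, as.integer(round(spec$ionomycin_ramp_s / spec$dt)))
  n_plat <- max(1L, as.integer(round(spec$ionomycin_plateau_s / spec$dt)))
  c(n_win + n_ramp + 1L, n_win + n_ramp + n_plat)
}

#' Expected event rate after refractory thinning
#'
#' A Poisson process of rate lambda passed through a non-paralyzable dead
#' time r has equilibrium output rate `lambda / (1 + lambda * r)`.
#'
#' @param spec A [synthetic_spec()].
#' @return Expected thinned event rate in events per minute.
#' @export
expected_thinned_rate <- function(spec) {
  lambda_s <- spec$event_rate_per_min / 60
  60 * lambda_s / (1 + lambda_s * spec$refractory_s)
}

#' Score detections against ground truth
#'
#' Greedy one-to-one matching of detected peaks to true event frames: all
#' candidate pairs within `tol_frames` are ranked by absolute frame
#' distance (ties broken by earlier true event) and accepted greedily so
#' each true event matches at most one detection and vice versa.
#' Sensitivity is matched / true; precision is matched / detected.
#'
#' @param truth Per-cell ground truth from [simulate_cell()].
#' @param result A `detection_result` for the same cell.
#' @param tol_frames Matching tolerance in frames.
#' @return List with `sensitivity`, `precision` (`NA` when there are no
#'   true events or no detections, respectively), `n_true`, `n_detected`,
#'   `n_matched`, and `matches` (data frame `true_frame`,
#'   `detected_frame`).
#' @export
score_detection <- function(truth, result, tol_frames = 3L) {
  if (!inherits(result, "detection_result")) stop("result must be a detection_result", call. = FALSE)
  if (!identical(truth$cell_id, result$cell_id)) {
    stop(sprintf("cell_id mismatch: truth '%s' vs result '%s'",
                 truth$cell_id, result$cell_id), call. = FALSE)
  }
  tol_frames <- as.integer(tol_frames)
  if (is.na(tol_frames) || tol_frames < 0L) stop("tol_frames must be >= 0", call. = FALSE)
  tf <- truth$event_frames
  df <- result$events$peak_frame
  pairs <- expand.grid(ti = seq_along(tf), di = seq_along(df))
  if (nrow(pairs) > 0L) {
    pairs$dist <- abs(tf[pairs$ti] - df[pairs$di])
    pairs <- pairs[pairs$dist <= tol_frames, , drop = FALSE]
    pairs <- pairs[order(pairs$dist, pairs$ti), , drop = FALSE]
  }
  used_t <- logical(length(tf)); used_d <- logical(length(df))
  mt <- integer(0); md <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    ti <- pairs$ti[r]; di <- pairs$di[r]
    if (!used_t[ti] && !used_d[di]) {
      used_t[ti] <- TRUE; used_d[di] <- TRUE
      mt <- c(mt, ti); md <- c(md, di)
    }
  }
  n_matched <- length(mt)
  list(
    sensitivity = if (length(tf) > 0L) n_matched / length(tf) else NA_real_,
    precision = if (length(df) > 0L) n_matched / length(df) else NA_real_,
    n_true = length(tf), n_detected = length(df), n_matched = n_matched,
    matches = data.frame(true_frame = tf[mt], detected_frame = df[md])
  )
}
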