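#' Construct a fluorescence trace
#'
#' One cell's fluorescence-intensity time series, sampled at a fixed frame
#' interval, together with the analysis window (the spontaneous-activity
#' segment recorded before ionomycin addition). Frames are indexed 1-based
#' and windows are inclusive on both ends.
#'
#' @param values Numeric vector of non-negative intensities, one per frame.
#'   Arbitrary fluorescence units, or dimensionless F/Fmax after
#'   normalization.
#' @param cell_id Character scalar identifying the cell.
#' @param dt Frame interval in seconds. The default 0.478 s matches a common
#'   confocal time-series resolution for spontaneous cortical cultures.
#' @param window Integer pair `c(a, b)`, inclusive frame indices of the
#'   analysis window. Defaults to the whole trace.
#' @param normalized Logical; `TRUE` once values are F/Fmax.
#' @return An object of class `fluorescence_trace`.
#' @seealso [validate_trace()]
#' @export
fluorescence_trace <- function(values, cell_id = "cell", dt = 0.478,
                               window = c(1L, length(values)),
                               normalized = FALSE) {
  trace <- structure(
    list(
      cell_id = as.character(cell_id),
      values = as.numeric(values),
      dt = as.numeric(dt),
      window = as.integer(round(window)),
      normalized = isTRUE(normalized)
    ),
    class = "fluorescence_trace"
  )
  validate_trace(trace)
}

#' Validate a fluorescence trace
#'
#' Checks the trace invariants: at least one finite, non-negative value;
#' a positive frame interval; an in-range inclusive window; and, for
#' normalized traces, a ceiling of 1 (plus tolerance) set by the saturation
#' segment.
#'
#' @param trace A [fluorescence_trace()].
#' @param norm_tol Slack allowed above 1 for normalized traces: noise on the
#'   saturation plateau pushes single frames past Fmax, so the ceiling must
#'   tolerate the largest plausible noise excursion (0.2 is ten times a
#'   typical 2% plateau noise sd).
#' @return The trace, unchanged, if all invariants hold; otherwise an error
#'   naming the violated invariant.
#' @export
validate_trace <- function(trace, norm_tol = 0.2) {
  if (!inherits(trace, "fluorescence_trace")) {
    stop("not a fluorescence_trace object", call. = FALSE)
  }
  v <- trace$values
  if (length(v) < 1L) stop("empty series: trace must have at least one frame", call. = FALSE)
  bad <- which(!is.finite(v))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite value at frame %d", bad[1L]), call. = FALSE)
  }
  neg <- which(v < 0)
  if (length(neg) > 0L) {
    stop(sprintf("negative value at frame %d", neg[1L]), call. = FALSE)
  }
  if (!is.finite(trace$dt) || trace$dt <= 0) {
    stop("non-positive dt: frame interval must be > 0 seconds", call. = FALSE)
  }
  w <- trace$window
  if (length(w) != 2L || anyNA(w)) stop("window must be two frame indices", call. = FALSE)
  if (w[1L] < 1L || w[2L] > length(v) || w[1L] > w[2L]) {
    stop(sprintf("window out of range: [%d, %d] for %d frames", w[1L], w[2L], length(v)),
         call. = FALSE)
  }
  if (trace$normalized && max(v) > 1 + norm_tol) {
    stop(sprintf("normalized trace exceeds Fmax ceiling: max %.3f > %.3f",
                 max(v), 1 + norm_tol), call. = FALSE)
  }
  trace
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> cell %s: %d frames @ %.3f s (%s), window [%d, %d]\n",
              x$cell_id, length(x$values), x$dt,
              if (x$normalized) "F/Fmax" else "raw", x$window[1L], x$window[2L]))
  invisible(x)
}

#' Transient-detection parameters
#'
#' The delta/theta/gamma triple governing the windowed detection rule, plus
#' the merge gap used to collapse plateau (tied) detections into single
#' events.
#'
#' A frame n is a transient peak when (i) F(n) is a local maximum over
#' `[n - delta, n + delta]` and (ii) F(n) exceeds the local mean over
#' `[n - theta, n + theta]` by the relative excess `gamma`:
#' `F(n) > (1 + gamma) / (2 theta + 1) * sum(F[n - theta .. n + theta])`.
#'
#' @param delta Non-negative integer, local-maximum half-window in frames.
#' @param theta Positive integer, local-mean half-window in frames.
#' @param gamma Non-negative real, relative threshold excess over the local
#'   mean.
#' @param merge_gap Non-negative integer; qualifying frames closer than or
#'   equal to this many frames apart are collapsed into one event. Defaults
#'   to `delta`, the natural locality scale of the rule.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(delta = 3L, theta = 7L, gamma = 0.25,
                             merge_gap = delta) {
  delta <- as.integer(delta); theta <- as.integer(theta)
  merge_gap <- as.integer(merge_gap)
  if (is.na(delta) || delta < 0L) stop("delta must be a non-negative integer", call. = FALSE)
  if (is.na(theta) || theta < 1L) stop("theta must be a positive integer", call. = FALSE)
  if (!is.finite(gamma) || gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  if (is.na(merge_gap) || merge_gap < 0L) stop("merge_gap must be non-negative", call. = FALSE)
  structure(list(delta = delta, theta = theta, gamma = as.numeric(gamma),
                 merge_gap = merge_gap),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf("<detection_params> delta=%d theta=%d gamma=%g merge_gap=%d\n",
              x$delta, x$theta, x$gamma, x$merge_gap))
  invisible(x)
}

#' Calibration parameters for absolute calcium concentration
#'
#' Fmin is the fluorescence floor measured in zero-calcium buffer with the
#' chelator BAPTA-AM; Fmax is the ionomycin-saturated ceiling; Kd is the
#' indicator's dissociation constant. Kd has no default: it depends on the
#' indicator and conditions (for the Fluo-4 class of single-wavelength dyes
#' values around 300-350 nM are typical at room temperature) and must be
#' supplied explicitly.
#'
#' @param f_min Fluorescence in the zero-calcium/BAPTA condition.
#' @param f_max Fluorescence at calcium saturation (ionomycin).
#' @param kd_nM Indicator dissociation constant in nM.
#' @return An object of class `calibration_params`.
#' @seealso [absolute_calcium()]
#' @export
calibration_params <- function(f_min, f_max, kd_nM) {
  if (!is.finite(f_min) || f_min < 0) stop("f_min must be >= 0", call. = FALSE)
  if (!is.finite(f_max) || f_max <= f_min) stop("f_max must exceed f_min", call. = FALSE)
  if (!is.finite(kd_nM) || kd_nM <= 0) stop("kd_nM must be > 0", call. = FALSE)
  structure(list(f_min = as.numeric(f_min), f_max = as.numeric(f_max),
                 kd_nM = as.numeric(kd_nM)),
            class = "calibration_params")
}

# Duration of an inclusive frame window, in seconds.
window_duration_s <- function(window, dt) {
  (window[2L] - window[1L] + 1L) * dt
}
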