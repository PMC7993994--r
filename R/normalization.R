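#' Estimate Fmax from the ionomycin saturation plateau
#'
#' After ionomycin is added at the end of a recording, cytosolic calcium
#' saturates the indicator and fluorescence settles on a plateau; its level
#' defines Fmax for the cell. The plateau is summarized by a robust
#' statistic; the median is the default because single-frame shot noise
#' should not set the normalization ceiling.
#'
#' @param trace A [fluorescence_trace()].
#' @param segment Integer pair `c(start, end)`, inclusive frame indices of
#'   the plateau. Must lie after the analysis window.
#' @param stat Summary statistic over the segment: `"median"` (default),
#'   `"mean"` or `"max"`.
#' @return Scalar Fmax estimate in the trace's units.
#' @export
estimate_fmax <- function(trace, segment, stat = c("median", "mean", "max")) {
  stat <- match.arg(stat)
  validate_trace(trace)
  segment <- as.integer(round(segment))
  if (length(segment) != 2L || anyNA(segment)) {
    stop("segment must be two frame indices", call. = FALSE)
  }
  if (segment[1L] > segment[2L] || segment[1L] < 1L ||
      segment[2L] > length(trace$values)) {
    stop("empty or out-of-range saturation segment", call. = FALSE)
  }
  if (segment[1L] <= trace$window[2L]) {
    stop("saturation segment must lie after the analysis window", call. = FALSE)
  }
  v <- trace$values[segment[1L]:segment[2L]]
  switch(stat,
         median = stats::median(v),
         mean = mean(v),
         max = max(v))
}

#' Normalize a trace to calcium-saturated fluorescence
#'
#' Divides every value by Fmax so that signals are comparable across cells:
#' the saturation plateau maps to 1 and spontaneous activity lives below it.
#'
#' @param trace A [fluorescence_trace()].
#' @param fmax Positive scalar, typically from [estimate_fmax()].
#' @return The trace with values divided by `fmax` and the `normalized`
#'   flag set; `dt`, window and cell id are unchanged.
#' @export
normalize_to_fmax <- function(trace, fmax) {
  validate_trace(trace)
  if (!is.finite(fmax) || fmax <= 0) stop("fmax must be > 0", call. = FALSE)
  trace$values <- trace$values / fmax
  trace$normalized <- TRUE
  validate_trace(trace)
}

#' Estimate a per-frame baseline by a rolling percentile filter
#'
#' For sparse-transient traces a low percentile over a sliding window tracks
#' the resting level while ignoring the brief excursions. The window is
#' centered and truncated at the trace ends; the estimate is additionally
#' capped at the running maximum of the trace so the baseline can never
#' anticipate a rise that has not yet been observed.
#'
#' @param trace A [fluorescence_trace()] or numeric vector.
#' @param method Baseline method; only `"rolling_percentile"` is
#'   implemented.
#' @param window_frames Window width in frames (default 21, about 10 s at
#'   0.478 s frames).
#' @param percentile Percentile in (0, 100); default 20.
#' @return Numeric vector, one baseline value per frame.
#' @export
estimate_baseline <- function(trace, method = "rolling_percentile",
                              window_frames = 21L, percentile = 20) {
  method <- match.arg(method, "rolling_percentile")
  v <- if (inherits(trace, "fluorescence_trace")) trace$values else as.numeric(trace)
  window_frames <- as.integer(window_frames)
  if (is.na(window_frames) || window_frames < 1L) {
    stop("window_frames must be >= 1", call. = FALSE)
  }
  if (window_frames > length(v)) {
    stop("baseline window larger than trace", call. = FALSE)
  }
  if (!is.finite(percentile) || percentile <= 0 || percentile >= 100) {
    stop("percentile must be in (0, 100)", call. = FALSE)
  }
  p <- percentile / 100
  base <- rolling_percentile(v, seq_along(v), window_frames, p)
  pmin(base, cummax(v))
}

# Centered rolling percentile of v evaluated at the requested frames only;
# windows are truncated at the trace ends.
rolling_percentile <- function(v, at, width, p) {
  before <- (width - 1L) %/% 2L
  after <- width - 1L - before
  len <- length(v)
  vapply(at, function(n) {
    stats::quantile(v[max(1L, n - before):min(len, n + after)],
                    probs = p, names = FALSE, type = 7)
  }, numeric(1))
}

#' Convert normalized fluorescence to absolute calcium concentration
#'
#' Single-wavelength (non-ratiometric) indicator calibration:
#' `[Ca] = Kd * (F - Fmin) / (Fmax - F)`, with Fmin from the
#' zero-calcium/BAPTA condition and Fmax from ionomycin saturation. The
#' conversion is strictly increasing in F and diverges as F approaches
#' Fmax, where the indicator saturates.
#'
#' @param f Fluorescence value(s), same units as the calibration; must
#'   satisfy `f_min <= f < f_max`.
#' @param calib A [calibration_params()].
#' @return Calcium concentration(s) in nM.
#' @export
absolute_calcium <- function(f, calib) {
  if (!inherits(calib, "calibration_params")) {
    stop("calib must be calibration_params", call. = FALSE)
  }
  if (any(!is.finite(f))) stop("f must be finite", call. = FALSE)
  if (any(f < calib$f_min)) stop("f below Fmin floor", call. = FALSE)
  if (any(f >= calib$f_max)) {
    stop("f at or above Fmax: indicator saturated, concentration undefined",
         call. = FALSE)
  }
  calib$kd_nM * (f - calib$f_min) / (calib$f_max - f)
}
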