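#' Write traces to a wide CSV table
#'
#' First column `time_s`, then one column per cell id, header row required.
#' Values are written with 17 significant digits so a round trip through
#' the file reproduces them to machine precision. All traces must share the
#' same frame grid.
#'
#' @param traces List of [fluorescence_trace()] objects on a common grid.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "fluorescence_trace")) traces <- list(traces)
  lens <- vapply(traces, function(x) length(x$values), integer(1))
  dts <- vapply(traces, `[[`, numeric(1), "dt")
  if (length(unique(lens)) != 1L || length(unique(dts)) != 1L) {
    stop("all traces must share the same length and dt", call. = FALSE)
  }
  ids <- vapply(traces, `[[`, character(1), "cell_id")
  if (anyDuplicated(ids)) stop("duplicate cell ids", call. = FALSE)
  time_s <- (seq_len(lens[1L]) - 1) * dts[1L]
  cols <- c(list(sprintf("%.17g", time_s)),
            lapply(traces, function(x) sprintf("%.17g", x$values)))
  lines <- c(paste(c("time_s", ids), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read traces from a wide CSV table
#'
#' Expects the layout written by [write_traces()]: a `time_s` column and
#' one column per cell. Lines starting with `#` are ignored. The frame
#' interval is taken from the time column.
#'
#' @param path CSV file path.
#' @param window Optional analysis window `c(a, b)` applied to every cell;
#'   defaults to the full trace.
#' @param normalized Whether the stored values are already F/Fmax.
#' @return List of [fluorescence_trace()] objects, one per cell column.
#' @export
read_traces <- function(path, window = NULL, normalized = FALSE) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("trace table must have a time_s column", call. = FALSE)
  if (ncol(df) < 2L) stop("trace table has no cell columns", call. = FALSE)
  tvec <- df[["time_s"]]
  dt <- if (length(tvec) > 1L) stats::median(diff(tvec)) else 1
  ids <- setdiff(names(df), "time_s")
  if (is.null(window)) window <- c(1L, nrow(df))
  lapply(ids, function(id) {
    fluorescence_trace(df[[id]], cell_id = id, dt = dt, window = window,
                       normalized = normalized)
  })
}

#' Write per-cell metrics to a tab-separated table
#'
#' Columns `cell_id, n_transients, firing_rate_per_min, clearance_time_s,
#' amplitude, mean_signal`. Missing metrics (cells without qualifying
#' transients) are written as empty fields, never as zero.
#'
#' @param metrics Data frame of row-bound [summarize_cell()] outputs.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  cols <- c("cell_id", "n_transients", "firing_rate_per_min",
            "clearance_time_s", "amplitude", "mean_signal")
  if (!all(cols %in% names(metrics))) {
    stop("metrics table missing required columns", call. = FALSE)
  }
  utils::write.table(metrics[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-cell metrics table written by [write_metrics()]
#'
#' @param path Tab-separated file path.
#' @return Data frame with empty fields read back as `NA`.
#' @export
read_metrics <- function(path) {
  utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE)
}

#' Write detected events to a tab-separated table
#'
#' Columns `cell_id, peak_frame, peak_time_s, peak_value, baseline,
#' amplitude, half_decay_s`; missing half-decays are empty fields.
#'
#' @param results A `detection_result` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(results, path) {
  if (inherits(results, "detection_result")) results <- list(results)
  tabs <- lapply(results, function(r) {
    if (nrow(r$events) == 0L) return(NULL)
    cbind(cell_id = r$cell_id, r$events)
  })
  tab <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  if (is.null(tab)) {
    tab <- data.frame(cell_id = character(0), peak_frame = integer(0),
                      peak_time_s = numeric(0), peak_value = numeric(0),
                      baseline = numeric(0), amplitude = numeric(0),
                      half_decay_s = numeric(0))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
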