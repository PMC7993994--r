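#' Build a pipeline run configuration
#'
#' Collects everything one analysis run needs: input traces, detection and
#' normalization settings, optional group labels for a two-group
#' comparison, and a seed recorded in the run manifest.
#'
#' @param traces Path to a wide trace CSV (see [read_traces()]) or a list
#'   of [fluorescence_trace()] objects.
#' @param out_dir Output directory; created if absent.
#' @param params A [detection_params()].
#' @param window Optional analysis window `c(a, b)` overriding the traces'
#'   own windows.
#' @param fmax_segment Optional saturation segment `c(start, end)`; when
#'   given, raw traces are normalized to the Fmax estimated over it.
#' @param fmax_stat Statistic for [estimate_fmax()].
#' @param baseline_window,baseline_percentile Baseline-filter settings.
#' @param groups Optional named character vector mapping every cell id to a
#'   group label; exactly two labels trigger the group comparison.
#' @param var_equal Use the pooled-variance t-test in the comparison.
#' @param calibration Optional [calibration_params()]; when given, the
#'   metrics table gains `mean_ca_nM`, the mean signal converted to
#'   absolute calcium concentration.
#' @param seed Integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the config is replayed together
#'   with simulation).
#' @return An object of class `run_config`.
#' @export
run_config <- function(traces, out_dir, params = detection_params(),
                       window = NULL, fmax_segment = NULL,
                       fmax_stat = "median",
                       baseline_window = 21L, baseline_percentile = 20,
                       groups = NULL, var_equal = FALSE,
                       calibration = NULL, seed = 1L) {
  structure(list(traces = traces, out_dir = out_dir, params = params,
                 window = window, fmax_segment = fmax_segment,
                 fmax_stat = fmax_stat,
                 baseline_window = as.integer(baseline_window),
                 baseline_percentile = baseline_percentile,
                 groups = groups, var_equal = isTRUE(var_equal),
                 calibration = calibration, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys: `traces`, `out_dir`, `detection` (delta, theta, gamma,
#' merge_gap), `window` (a, b), `fmax` (segment: [start, end], stat),
#' `baseline` (window_frames, percentile), `calibration` (f_min, f_max,
#' kd_nM), `groups` (cell_id: label map), `var_equal`, `seed`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$traces) || is.null(y$out_dir)) {
    stop("config must set traces and out_dir", call. = FALSE)
  }
  det <- y$detection
  params <- if (is.null(det)) detection_params() else do.call(detection_params, det)
  calib <- if (is.null(y$calibration)) NULL else do.call(calibration_params, y$calibration)
  run_config(
    traces = y$traces, out_dir = y$out_dir, params = params,
    window = if (is.null(y$window)) NULL else as.integer(unlist(y$window)),
    fmax_segment = if (is.null(y$fmax$segment)) NULL else as.integer(unlist(y$fmax$segment)),
    fmax_stat = if (is.null(y$fmax$stat)) "median" else y$fmax$stat,
    baseline_window = if (is.null(y$baseline$window_frames)) 21L else y$baseline$window_frames,
    baseline_percentile = if (is.null(y$baseline$percentile)) 20 else y$baseline$percentile,
    groups = if (is.null(y$groups)) NULL else unlist(y$groups),
    var_equal = isTRUE(y$var_equal),
    calibration = calib,
    seed = if (is.null(y$seed)) 1L else y$seed
  )
}

#' Run the full trace-analysis pipeline
#'
#' Executes validate, Fmax estimation, normalization, transient detection
#' and per-cell summarization for every cell, then (when two group labels
#' are configured) the per-metric two-group comparison. Writes
#' `events.tsv`, `metrics.tsv`, optionally `comparison.tsv`, a
#' `manifest.json` capturing parameters, versions, seed and input
#' checksums, and `run.log` with per-cell warnings. Reruns with identical
#' config and inputs produce byte-identical tables.
#'
#' @param config A [run_config()] or path to a YAML config.
#' @return Invisibly, a report list: `metrics`, `events` (list of
#'   `detection_result`), `comparison` (data frame or `NULL`), `manifest`,
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  if (!inherits(config, "run_config")) stop("config must be a run_config", call. = FALSE)

  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  input_md5 <- NULL
  traces <- config$traces
  if (is.character(traces)) {
    if (!file.exists(traces)) stop(sprintf("trace file not found: %s", traces), call. = FALSE)
    input_md5 <- unname(tools::md5sum(traces))
    traces <- read_traces(traces, window = config$window)
  } else if (!is.null(config$window)) {
    traces <- lapply(traces, function(tr) {
      tr$window <- as.integer(config$window); validate_trace(tr)
    })
  }
  ids <- vapply(traces, `[[`, character(1), "cell_id")

  if (!is.null(config$groups)) {
    missing_ids <- setdiff(ids, names(config$groups))
    if (length(missing_ids) > 0L) {
      stop(sprintf("group labels missing for cells: %s",
                   paste(missing_ids, collapse = ", ")), call. = FALSE)
    }
  }

  results <- vector("list", length(traces))
  metrics <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- validate_trace(traces[[i]])
    if (!tr$normalized) {
      if (!is.null(config$fmax_segment)) {
        fmax <- estimate_fmax(tr, config$fmax_segment, stat = config$fmax_stat)
        tr <- normalize_to_fmax(tr, fmax)
      } else {
        note("cell %s: no fmax segment configured; analyzing raw trace", tr$cell_id)
      }
    }
    res <- suppressMessages(detect_transients(
      tr, config$params,
      baseline_window = config$baseline_window,
      baseline_percentile = config$baseline_percentile
    ))
    if (nrow(res$events) == 0L) note("cell %s: zero transients detected", tr$cell_id)
    results[[i]] <- res
    metrics[[i]] <- summarize_cell(res, tr)
  }
  metrics <- do.call(rbind, c(metrics, list(make.row.names = FALSE)))

  if (!is.null(config$calibration)) {
    f <- pmin(metrics$mean_signal, config$calibration$f_max - 1e-9)
    metrics$mean_ca_nM <- absolute_calcium(pmax(f, config$calibration$f_min),
                                           config$calibration)
  }

  comparison <- NULL
  if (!is.null(config$groups)) {
    labels <- unique(unname(config$groups))
    if (length(labels) == 2L) {
      in_a <- metrics$cell_id %in% names(config$groups)[config$groups == labels[1L]]
      fields <- c("firing_rate_per_min", "clearance_time_s", "amplitude", "mean_signal")
      rows <- lapply(fields, function(f) {
        cmp <- compare_groups(metrics[in_a, ], metrics[!in_a, ], f,
                              var_equal = config$var_equal)
        data.frame(field = f, group_a = labels[1L], group_b = labels[2L],
                   mean_a = cmp$mean_a, sem_a = cmp$sem_a, n_a = cmp$n_a,
                   mean_b = cmp$mean_b, sem_b = cmp$sem_b, n_b = cmp$n_b,
                   t_statistic = cmp$statistic, p_value = cmp$p_value,
                   stringsAsFactors = FALSE)
      })
      comparison <- do.call(rbind, rows)
    } else {
      note("groups present but %d labels found; comparison needs exactly 2",
           length(labels))
    }
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    events = file.path(config$out_dir, "events.tsv"),
    metrics = file.path(config$out_dir, "metrics.tsv"),
    manifest = file.path(config$out_dir, "manifest.json"),
    log = file.path(config$out_dir, "run.log")
  )
  write_events(results, paths$events)
  if (is.null(config$calibration)) {
    write_metrics(metrics, paths$metrics)
  } else {
    utils::write.table(metrics, paths$metrics, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  if (!is.null(comparison)) {
    paths$comparison <- file.path(config$out_dir, "comparison.tsv")
    utils::write.table(comparison, paths$comparison, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }

  manifest <- list(
    package = "catrace",
    package_version = as.character(utils::packageVersion("catrace")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    detection = unclass(config$params),
    window = config$window,
    fmax = list(segment = config$fmax_segment, stat = config$fmax_stat),
    baseline = list(window_frames = config$baseline_window,
                    percentile = config$baseline_percentile),
    n_cells = length(traces),
    input_md5 = input_md5,
    firing_rate_units = "transients per minute over the analysis window"
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  writeLines(log_lines, paths$log)

  invisible(list(metrics = metrics, events = results,
                 comparison = comparison, manifest = manifest,
                 paths = paths))
}

#' Evaluate detection and parameter recovery on synthetic cohorts
#'
#' For each replicate, simulates a cohort, runs the Fmax-normalization and
#' detection pipeline, scores detections against ground truth, and
#' measures how well the per-cell statistics recover the generative
#' parameters. Replicate r uses seed `spec$seed + r - 1`.
#'
#' @param spec A [synthetic_spec()].
#' @param params A [detection_params()].
#' @param n_reps Number of replicate cohorts.
#' @param tol_frames Matching tolerance for [score_detection()]; defaults
#'   to `params$delta`.
#' @return Data frame with one row per replicate: `rep`, `seed`,
#'   `sensitivity`, `precision` (cell means), `firing_rate_per_min`,
#'   `expected_rate_per_min`, `rate_rel_err`, `mean_amplitude`,
#'   `amplitude_rel_err`, `mean_clearance_s`, `clearance_err_s` (against
#'   `tau_s * log(2)`). Aggregate means and normal-approximation 95% CIs
#'   are attached as attribute `"aggregate"`.
#' @export
evaluate_pipeline <- function(spec, params = detection_params(),
                              n_reps = 1L, tol_frames = params$delta) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec", call. = FALSE)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)

  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sp <- spec
    sp$seed <- spec$seed + r - 1L
    cohort <- simulate_cohort(sp)
    seg <- saturation_segment(sp)
    sens <- prec <- numeric(sp$n_cells)
    mets <- vector("list", sp$n_cells)
    for (i in seq_len(sp$n_cells)) {
      tr <- cohort$traces[[i]]
      fmax <- estimate_fmax(tr, seg)
      trn <- normalize_to_fmax(tr, fmax)
      res <- detect_transients(trn, params)
      sc <- score_detection(cohort$truth[[i]], res, tol_frames = tol_frames)
      sens[i] <- sc$sensitivity
      prec[i] <- sc$precision
      mets[[i]] <- summarize_cell(res, trn)
    }
    mets <- do.call(rbind, mets)
    # events live on the interior interval; express their expected count as
    # a rate over the full analysis window, matching firing_rate_per_min
    interval_s <- sp$duration_s - 2 * sp$edge_margin_s - sp$rise_frames * sp$dt
    exp_rate <- expected_thinned_rate(sp) * interval_s / sp$duration_s
    rate <- mean(mets$firing_rate_per_min)
    amp <- mean(mets$amplitude, na.rm = TRUE)
    clr <- mean(mets$clearance_time_s, na.rm = TRUE)
    rows[[r]] <- data.frame(
      rep = r, seed = sp$seed,
      sensitivity = mean(sens, na.rm = TRUE),
      precision = mean(prec, na.rm = TRUE),
      firing_rate_per_min = rate,
      expected_rate_per_min = exp_rate,
      rate_rel_err = (rate - exp_rate) / exp_rate,
      mean_amplitude = amp,
      amplitude_rel_err = (amp - sp$amplitude_mean) / sp$amplitude_mean,
      mean_clearance_s = clr,
      clearance_err_s = clr - sp$tau_s * log(2)
    )
  }
  out <- do.call(rbind, rows)
  agg <- lapply(out[, -(1:2)], function(x) {
    m <- mean(x); se <- stats::sd(x) / sqrt(length(x))
    c(mean = m, ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
  })
  attr(out, "aggregate") <- agg
  out
}
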