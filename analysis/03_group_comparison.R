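#!/usr/bin/env Rscript
# Two-group contrast on per-cell metrics: a "control" cohort with decay
# tau = 1.5 s against a "fast-clearance" cohort with tau = 1.0 s (same
# rate, amplitude and noise), compared per metric by an unpaired two-tailed
# t-test — the desk-scale analogue of contrasting genotypes cell-by-cell.

library(catrace)

dir.create("results", showWarnings = FALSE)

sim_group <- function(tau_s, seed, label) {
  spec <- synthetic_spec(n_cells = 50, tau_s = tau_s, seed = seed)
  cohort <- simulate_cohort(spec)
  for (i in seq_along(cohort$traces)) {
    cohort$traces[[i]]$cell_id <- sprintf("%s_%03d", label, i)
  }
  list(traces = cohort$traces, seg = saturation_segment(spec))
}

ctrl <- sim_group(1.5, seed = 11, label = "ctrl")
fast <- sim_group(1.0, seed = 12, label = "fast")

traces <- c(ctrl$traces, fast$traces)
groups <- setNames(rep(c("ctrl", "fast"), each = 50),
                   vapply(traces, `[[`, character(1), "cell_id"))

report <- run_pipeline(run_config(
  traces = traces, out_dir = "results/groups",
  fmax_segment = ctrl$seg, groups = groups
))

cmp <- report$comparison
print(cmp, digits = 3)
clr <- cmp[cmp$field == "clearance_time_s", ]
cat(sprintf("\nclearance time: %.2f vs %.2f s (t = %.1f, p = %.3g)\n",
            clr$mean_a, clr$mean_b, clr$t_statistic, clr$p_value))
cat("the generative rate and amplitude are equal by construction; the dominant\n")
cat("contrast is clearance time, with small tau-dependent side effects on the\n")
cat("other detected metrics (shorter transients shift the detector's operating point)\n")
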