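# catrace

Analysis of per-cell fluorescence time series from calcium imaging of
spontaneously active neurons. The package takes soma-ROI intensity traces
(one value per frame per cell), normalizes them to the ionomycin-saturated
fluorescence ceiling Fmax, detects calcium transients with a windowed
threshold rule, and quantifies each cell by its firing rate, transient
amplitude, calcium clearance time and mean signal — the quantities used to
compare neuronal calcium handling between groups of cells (e.g. genotypes)
with an unpaired t-test. A single-wavelength Fmin/Fmax/Kd calibration
converts normalized fluorescence to absolute calcium concentration.

It is written for experimentalists who have already extracted traces from
their movies (ROI segmentation is out of scope) and want a reproducible,
tested implementation of the downstream numbers.

## The method

Traces are first divided by **Fmax**, estimated as the median of the
post-ionomycin saturation plateau, giving dimensionless F/Fmax signals. A
frame *n* is a transient peak when both

* F(n) ≥ F(a) for every a ∈ [n−δ, n+δ]   (local maximum), and
* F(n) > (1+γ)/(2θ+1) · Σ_{j=n−θ}^{n+θ} F(j)   (exceeds the local mean by the relative margin γ),

with δ = 3, θ = 7, γ = 0.25 frames as the working setting at 478 ms frame
intervals. Tied flat-top detections merge to one event. Per cell, the
package reports:

* **N, firing rate** — transient count over the analysis window, per minute;
* **T, clearance time** — time from each peak to baseline + amplitude/2
  (linear interpolation; τ·ln 2 for an exponential decay with constant τ),
  averaged over events; missing, never zero, when no event has a defined
  half-decay;
* **A, amplitude** — F(peak) minus a rolling-percentile baseline, averaged
  over events;
* **Mean** — mean F/Fmax over the analysis window;
* **[Ca²⁺] = Kd·(F − Fmin)/(Fmax − F)** when a calibration is supplied.

Because no trace data are publicly deposited for this analysis, the package
includes a synthetic-trace generator with ground truth (Poisson events with
refractory thinning, lognormal amplitudes, exponential decay, noise, drift
and a terminal ionomycin plateau) so detection and every summary statistic
are verifiable against known truth. See the methods vignette
(`vignettes/calcium-trace-analysis.Rmd`) for the full model, parameter
rationale and an honest analysis of the detector's operating point.

## Worked example

```r
library(catrace)

spec <- synthetic_spec(n_cells = 1, seed = 42)   # 478 s window @ 478 ms frames
sim  <- simulate_cell(spec, 1)

fmax  <- estimate_fmax(sim$trace, saturation_segment(spec))
trace <- normalize_to_fmax(sim$trace, fmax)
res   <- detect_transients(trace, detection_params(3, 7, 0.25))
summarize_cell(res, trace)
score_detection(sim$truth, res, tol_frames = 3)
```

prints

```
Fmax estimate: 2.000 (truth 2.0)
<detection_result> cell cell_001: 41 events in window [1, 1000]
   cell_id n_transients firing_rate_per_min clearance_time_s amplitude mean_signal
1 cell_001           41                5.15             1.01     0.227       0.188
vs ground truth: 36/36 events found, sensitivity 1.00, precision 0.88
```

All 36 true transients are recovered (the extra detections are noise peaks
clearing the relative threshold — see the vignette's operating-point
discussion). The clearance time 1.01 s agrees with the generator's decay
constant, τ·ln 2 = 1.5·0.693 ≈ 1.04 s.

The `analysis/` scripts chain the same calls into the full workflow —
`01_simulate.R` (reference cohort), `02_detect.R` (normalization, detection
and per-cell metrics, written to `results/run/`), `03_group_comparison.R`
(two cohorts differing only in decay τ, compared per metric; the τ = 1.5 vs
1.0 s contrast gives clearance times 0.91 vs 0.69 s, t = 24.5) and
`04_evaluate_detection.R` (ground-truth scoring over 20 cohorts of 50
cells). For file-based runs, `run_pipeline(run_config(...))` (or a YAML
config) reads a wide trace CSV and writes events, metrics, comparison
tables and a run manifest.

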