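---
title: "Methods: calcium trace normalization, transient detection and per-cell statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium trace normalization, transient detection and per-cell statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`catrace` analyzes per-cell fluorescence time series from calcium imaging of
spontaneously active neurons expressing a single-wavelength indicator
(GCaMP6f or Fluo-4 class). Each recording consists of a spontaneous-activity
segment — the analysis window — followed by application of the ionophore
ionomycin, which saturates the indicator and drives fluorescence to its
ceiling Fmax. The pipeline is:

1. normalize each trace to its Fmax, so signals are dimensionless F/Fmax and
   comparable across cells;
2. detect calcium transients with a windowed local-maximum / local-mean
   threshold rule;
3. summarize each cell by four statistics: transient count N (reported as a
   firing rate), mean half-amplitude clearance time T, mean transient
   amplitude A, and the mean signal over the analysis window;
4. optionally compare two groups of cells metric-by-metric with an unpaired
   two-tailed t-test, and convert normalized fluorescence to absolute
   calcium concentration when an Fmin/Fmax/Kd calibration is available.

Because no public trace data accompany the analysis, the package ships a
synthetic-trace generator with ground truth so that every stage is testable:
detection is scored against known event times, and the per-cell statistics
are checked against the generative parameters.

# The detection rule

A frame $n$ of the (normalized) signal $F$ is a transient peak when both

* **local maximum**: $F(n) \ge F(a)$ for every $a \in [n-\delta,\, n+\delta]$, and
* **local-mean excess**: $F(n) > \dfrac{1+\gamma}{2\theta+1} \sum_{j=n-\theta}^{n+\theta} F(j)$,

with half-windows $\delta$ (local maximum) and $\theta$ (local mean) in
frames and a dimensionless relative excess $\gamma$. The working parameter
setting is $\delta = 3$, $\theta = 7$, $\gamma = 0.25$; at 478 ms frames
these windows span about 3.3 s and 7.2 s of signal. Both conditions are
homogeneous in $F$, so detection is invariant under positive rescaling of
the trace — normalization changes no peak — while additive offsets are not
neutral: a constant added to the trace inflates the local mean and
suppresses detections. This is why the pipeline divides by Fmax rather than
subtracting a background.

Three behaviors of the rule require explicit decisions:

* **Complete windows only.** The rule indexes $n-\theta \dots n+\theta$
  without edge handling, so frames within $\max(\delta, \theta)$ of either
  end of the trace or the analysis window are never tested. Partial-window
  semantics would be silent and untestable.
* **Plateau ties.** The local-maximum condition uses $\ge$, so a flat-topped
  transient qualifies at several consecutive frames. Runs of qualifying
  frames separated by at most `merge_gap` frames (default $\delta$, the
  rule's own locality scale) collapse to one event at the highest-$F$ frame,
  earliest frame on exact ties — one transient counts once.
* **Amplitude baseline.** The amplitude of an event is $F(\text{peak})$
  minus a per-frame baseline estimate at the peak. The baseline is a
  centered rolling 20th percentile over 21 frames (about 10 s), capped at
  the running maximum of the trace; a low percentile over a window several
  times longer than a transient tracks the resting level while ignoring the
  brief excursions. On zero-baseline traces amplitude reduces to the peak
  value itself, which the tests exploit.

# Clearance time

The clearance time of a transient is the time from its peak to the first
subsequent instant at which the signal falls to
$\text{baseline} + \text{amplitude}/2$, located by linear interpolation
between the bracketing frames. "Half of the amplitude" is read relative to
the event's baseline, matching the amplitude definition; on zero-baseline
traces the two possible readings coincide. For an exponential decay with
time constant $\tau$ this half-decay time equals $\tau \ln 2$ — the package
deliberately reports the half-amplitude crossing, not a fitted exponential
$\tau$; the two differ by exactly the factor $\ln 2$ when the decay is
exponential, and the crossing is defined for any decay shape.

The search for the crossing truncates at the next event's peak or at the
window end. A transient interrupted before reaching half amplitude
contributes a *missing* value to the cell's mean clearance time, never a
truncated time: truncated times would bias T downward precisely in the
cells that fire most. The same principle applies throughout — cells with no
qualifying transients have missing T and A, written as empty fields in
output tables, never zero.

# Per-cell statistics and units

For cell $i$ with $k_i$ detected events: $T_i$ and $A_i$ are arithmetic
means over events (over events with a defined half-decay, for $T_i$), and
the mean signal is the arithmetic mean of $F$ over the inclusive analysis
window $[a, b]$. Frames are indexed 1-based and windows are inclusive at
both ends; the window duration is $(b - a + 1)\,dt$. Firing rate is
$N_i$ divided by the window duration, reported **per minute** — a readable
unit for spontaneous cortical activity of a few events per minute; the unit
is recorded in the output header and the run manifest.

# Absolute calcium calibration

For a single-wavelength indicator with floor Fmin (zero-calcium buffer plus
the chelator BAPTA-AM) and ceiling Fmax (ionomycin),

$$[\mathrm{Ca}^{2+}] = K_d \,\frac{F - F_\min}{F_\max - F}.$$

The conversion is exact at its anchors ($0$ at Fmin, $K_d$ at the
midpoint), strictly increasing, and diverges at Fmax where the indicator
saturates; saturated or below-floor inputs are errors, not clamped values.
$K_d$ has **no default**: it depends on indicator and conditions (values
around 300–350 nM are typical for Fluo-4-class dyes at room temperature)
and must be supplied by the user. Fmin and Fmax enter as per-recording
scalars, mirroring how both conditions are applied to a whole culture.

# The synthetic generator

`synthetic_spec()` emulates the recording design: 478 ms frames, a 478 s
spontaneous window (1000 frames), then an ionomycin segment. Defaults, with
rationale:

| parameter | default | meaning |
|---|---|---|
| `event_rate_per_min` | 6 | Poisson event rate before refractory thinning |
| `refractory_s` | 3 | hard minimum gap; bursting cells do not restart mid-decay |
| `amplitude_mean`, `amplitude_cv` | 0.3, 0.25 | lognormal event amplitudes in F/Fmax units |
| `tau_s` | 1.5 | exponential decay constant, typical somatic GCaMP6f scale |
| `rise_frames` | 1 | rise is fast relative to the 478 ms frame |
| `baseline_level` | 0.15 | resting F/Fmax |
| `noise_sd` | 0.02 | additive Gaussian noise, i.e. peak SNR ≈ 15 |
| `drift_amplitude` | 0.01 | slow sinusoidal baseline drift (120 s period) |
| `fmax_raw` | 2.0 | raw-unit scale; plateau value of the raw trace |
| `edge_margin_s` | 5 | events confined to the window interior |

The trace is `fmax_raw * clip(baseline + drift + kernels + noise, 0)`;
clipping keeps fluorescence non-negative. The ionomycin segment ramps from
the resting level to the ceiling over 20 s and holds a noisy plateau for
60 s — much shorter than a real post-ionomycin recording, because only the
plateau's summary statistic matters and the median of ~125 plateau frames
already pins Fmax to a fraction of a percent. The edge margin keeps every
true transient fully observable: its peak inside the region the
complete-window rule can test, and its decay recorded. The event process is
Poisson with non-paralyzable dead time, whose equilibrium rate is
$\lambda/(1 + \lambda r)$ — at the defaults, 4.6 events/min — and the
thinning is validated in the tests against an independent Monte-Carlo
simulation of the point process alone.

Everything is a pure function of the spec including its seed (each cell
derives its own substream seed), so cohorts regenerate bit-identically.

What the generator does **not** emulate: movies and ROI extraction (traces
are the input here, segmentation was manual upstream), photobleaching,
indicator binding kinetics, temporally correlated noise, and network-driven
burst correlations between cells. Passing tests therefore demonstrate
correctness of the trace-level analysis under a plausible noise model, not
robustness to every artifact of real recordings.

# The detector's operating point, honestly measured

`evaluate_pipeline()` (driven by `analysis/04_evaluate_detection.R`)
replaces manual assessment of detection quality with ground-truth scoring:
greedy one-to-one matching of detected peaks to true events within ±3
frames, over 20 replicate cohorts of 50 cells — problem sizes chosen so the
full evaluation runs in seconds on a laptop.

At the reference regime the evaluation shows sensitivity ≈ 1.0 and
precision ≈ 0.80. The precision figure is not an accident of the seed: with
resting level 0.15 and noise sd 0.02 in normalized units, the local-mean
condition demands an excursion of roughly $\gamma \cdot 0.15 \approx 1.9$
noise standard deviations, and a local maximum clearing that bar occurs
about 9 times per 1000 frames of noise — against ~36 true events, that is
precision at almost exactly 80%. In other words, the published parameter
setting *operates at* an 80% effective-detection boundary rather than far
above it. Two downstream consequences are visible in the evaluation table
and worth knowing before interpreting absolute numbers: false detections at
the noise floor inflate the recovered firing rate (by roughly a quarter at
this regime) and, having near-zero amplitudes, dilute the mean amplitude by
a similar fraction. Mean clearance time is much less affected (within
~0.15 s of $\tau \ln 2$), because noise events rarely contribute a defined
half-decay. Group *contrasts* are robust to this shared bias — both groups
carry the same false-alarm load — which is the basis of the two-group
analysis in `analysis/03_group_comparison.R`.

# Group comparison

`compare_groups()` performs the unpaired two-tailed t-test on per-cell
values, excluding missing values with counts reported. Welch's
unequal-variance form is the default — per-cell variances have no reason to
be equal across genotypes or treatments — with the classic pooled-variance
Student form behind `var_equal = TRUE` for exact fidelity to the textbook
test. Cells are pooled across recordings as independent units, matching how
such panels are usually reported; nesting within animals or cultures is out
of scope. The test's size is verified empirically (type-I error within
[0.03, 0.07] at $\alpha = 0.05$ over 1000 null replicates), and a
clearance-time contrast between cohorts simulated with $\tau = 1.5$ versus
$1.0$ s separates at $p < 0.01$ with 50 cells per group.

# Numerical and degenerate-input choices

* Normalized traces may exceed 1 by at most 0.2 (ten times a typical
  plateau noise sd) — plateau noise necessarily pushes single frames past
  Fmax; anything larger indicates a wrong Fmax and is an error.
* The Fmax statistic is the plateau **median** (mean and max available):
  the ceiling should not be set by shot noise.
* Linear interpolation defines the half-amplitude crossing between frames;
  on noiseless exponentials this lands within one frame interval of
  $\tau \ln 2$ for any $\tau \ge$ a few frames.
* Tie-breaks are deterministic everywhere (earliest frame wins), so reruns
  are byte-identical; the run manifest records parameters, versions, seed
  and input checksums.
* Degenerate inputs fail loudly with the violated invariant named: empty
  traces, non-finite or negative values, out-of-range windows, saturation
  segments overlapping the analysis window, traces shorter than the rule's
  window.

# Known limitations

* Detection quality is quantified on synthetic traces; the 80%
  operating-point analysis above says what to expect, but real noise is not
  exactly Gaussian or white.
* The amplitude definition depends on the baseline estimator; other
  choices (e.g. pre-event mean) would shift A by a small systematic amount.
* No spike inference or deconvolution: the unit of analysis is the calcium
  transient, not the action potential.
* No bleaching correction and no ratiometric calibration.
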