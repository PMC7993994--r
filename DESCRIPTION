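Package: catrace
Title: Calcium Imaging Trace Analysis with Fmax Normalization and Transient Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis of per-cell fluorescence time series from calcium
    imaging of spontaneously active neurons. Normalizes traces to
    ionomycin-saturated fluorescence (Fmax), detects calcium transients with
    a windowed local-maximum / local-mean threshold rule (parameters delta,
    theta, gamma), and computes per-cell firing rate, transient amplitude,
    half-amplitude clearance time and mean signal. Converts normalized
    fluorescence to absolute calcium concentration via Fmin/Fmax single
    wavelength calibration. Ships a synthetic-trace generator with ground
    truth so every analysis stage is verifiable, detection scoring against
    ground truth, and an end-to-end pipeline with group comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    zoo,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
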