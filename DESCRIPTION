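Package: bpvar
Title: Blood Pressure Variability Indices from High-Resolution Arterial Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify blood pressure variability (BPV) in 1 Hz
    arterial blood-pressure records from neurocritical care monitoring.
    Implements artifact removal by a moving-average threshold filter with
    3-SD masking of extreme successive differences, two downsampling schemes
    (instantaneous sampling and bin averaging), five time-domain variability
    indices (SD, CV, ARV, SV, trend changes), discrete-Fourier band power in
    four physiological frequency bands, and nonparametric two-group outcome
    comparison (Mann-Whitney U, AUC with confidence intervals) with
    sampling-rate and monitoring-duration sweeps. Includes a synthetic-cohort
    generator with controlled band-limited spectral structure, injected
    artifacts and monitoring gaps for validation and power studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
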