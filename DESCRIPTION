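Package: eegselect
Title: Optimal EEG Electrode Subset Selection for Source Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated selection of minimal EEG electrode subsets that retain
    the source-localization accuracy of high-density montages. Couples the
    elitist multi-objective genetic algorithm NSGA-II with distributed inverse
    solvers (depth-weighted minimum-norm estimation and sLORETA), minimizing
    the number of channels and the per-source localization error jointly.
    Includes an analytic three-shell spherical head model for download-free
    lead fields, a ground-truth simulator of Gaussian-windowed sinusoidal
    cortical sources with exact SNR control, localization/waveform error
    metrics, pseudo-Pareto front extraction, and dataset-level summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
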