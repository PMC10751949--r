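Package: mparrm
Title: Matching-Pursuit Reconstruction and Removal of Electrical
    Stimulation Artifacts in Intracranial Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Removes single-pulse electrical stimulation (SPES) artifacts
    from intracranial electrophysiology signals on a trial-by-trial basis
    while preserving early (5-30 ms post-stimulus) spectral responses.
    Implements a greedy matching-pursuit decomposition over an over-complete
    dictionary of Gabor, sharp Gaussian, Dirac and Fourier atoms, a
    seven-step denoising pipeline that sequentially reconstructs and
    subtracts line noise, evoked potentials and the stimulation artifact,
    a synthetic-data generator (biphasic pulse-shape grids, saline-bath
    style artifact templates, SEEG-like ground-truth trials), and the full
    validation machinery: band-power envelopes, baseline z-scoring, binned
    Pearson correlation, sensitivity/specificity maps, fluctuation ratios,
    event-related spectral perturbations and early-peak detection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
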