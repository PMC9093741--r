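Package: olivetrace
Title: Calcium Imaging and Patch-Clamp Analysis of Inferior Olive Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for 1-photon GCaMP6s calcium imaging and paired
    whole-cell recordings of inferior olive (IO) neurons. Converts camera counts
    to calibrated light power, detects somatic calcium events and measures their
    rise times and amplitudes, quantifies 3-12 Hz subthreshold oscillations with
    Blackman-windowed Welch spectra, types membrane-voltage spike waveforms by
    PCA and k-means, and maps calcium-event rise times to electrophysiological
    spike widths through a linear calibration. Includes a synthetic-data
    generator that emulates IO membrane-voltage waveforms, the GCaMP6s
    fluorescence forward model with photon shot noise and camera dark noise, and
    two-channel anatomy images for neuron/astrocyte classification, each with a
    ground-truth manifest, plus the anatomical expression-profiling
    quantification (soma classification, normalized expression, structural
    specificity, nearest-neighbour spacing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
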