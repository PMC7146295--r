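Package: scgkit
Title: Unsupervised Heartbeat Detection and Morphology Embedding for
    Seismocardiogram Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and temporally annotates single heartbeats directly from
    chest-accelerometer (seismocardiogram, SCG) traces without concurrent ECG,
    using an energy-envelope detection signal, an adaptive sliding-window
    threshold, and per-subject template matching by cross-correlation. Segmented
    beats are embedded with a modular one-dimensional convolutional variational
    autoencoder, and the latent space is scored by unsupervised clustering.
    Includes ECG-referenced benchmarking (tolerance-window detection scores,
    inter-beat interval error statistics, Bland-Altman analysis, a Pan-Tompkins
    R-peak reference detector), an architecture-effect linear model, a
    multi-subject synthetic SCG+ECG cohort generator with ground truth, and
    readers/writers for WFDB and CSV records.
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
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
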