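Package: alphagate
Title: Prestimulus Alpha Power and Phase Effects on Awareness-Related ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested analysis pipeline linking prestimulus alpha-band (8-12 Hz)
    power and phase to stimulus-evoked ERP amplitude in the visual awareness
    negativity (VAN) window and to trial-level conscious perception. Provides an
    epoched-EEG container with a plain-text on-disk format, baseline correction
    and moving-window peak-to-peak artifact rejection, a Hanning-tapered
    complex-convolution time-frequency transform with band-specific cycle
    counts, circular statistics with a bootstrap preferred-phase procedure,
    trial-level feature extraction with tercile conditions, a two-stage
    circular-harmonic structural model (power x phase -> VAN -> perception)
    fitted by maximum likelihood with cluster-bootstrap intervals and
    BIC-approximated evidence, and a synthetic single-trial EEG generator with
    known ground truth so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
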