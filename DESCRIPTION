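Package: ratvar
Title: Autoregressive Spectral Analysis of Rat Cardiovascular Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Beat-to-beat analysis of arterial-pressure recordings in the rat:
    systolic-peak detection and pulse-interval extraction from pulsatile
    waveforms, stationary-fragment selection, autoregressive (Burg) spectral
    decomposition of tachograms and systograms into rat-specific VLF/LF/HF
    bands, sympathovagal balance (LF/HF) and the spontaneous baroreflex
    alpha index, and the 2x2 factorial (diabetes x renal denervation)
    statistical layer with Student-Newman-Keuls post-hoc comparisons.
    Includes a seeded synthetic-data generator for pulsatile pressure
    waveforms and per-animal cohorts so the whole pipeline is testable
    without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
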