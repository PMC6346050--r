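Package: striatune
Title: Auditory Striatum Single-Unit and Cloud-of-Tones Behavior Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for extracellular recordings from the auditory
    striatum and for a two-alternative forced-choice "cloud-of-tones"
    frequency-discrimination task. Classifies striatal single units (medium
    spiny neurons, fast-spiking and cholinergic interneurons) by spike
    half-valley width, detects tone-evoked response windows from peristimulus
    time histograms, builds frequency tuning curves with Gaussian
    receptive-field fits, decomposes pathway-silencing effects into a
    subtractive offset and a divisive gain, and fits logistic psychometric
    functions to behavioral sessions. Includes a seeded synthetic-data
    generator (inhomogeneous Poisson spike trains, parametric spike waveforms,
    Bernoulli choice behavior) that emulates the statistical structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
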