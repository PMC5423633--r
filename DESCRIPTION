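Package: vocalid
Title: Vocal Individuality and the Biases of Acoustic Discrimination of Individuals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing how reliably animal vocalizations identify
    individuals. Classifies calls to individuals by leave-one-out linear
    discriminant analysis on call features or by average spectrogram
    cross-correlation score, scores discrimination at the call and at the
    individual level (plurality rule over a calling bout), computes Beecher's
    information statistic H_S and the derived number of discriminable
    individuals N = P * 2^H_S, and runs resampling simulations quantifying how
    population size and the number of calls per individual bias discrimination
    performance. Includes a synthetic call-feature generator with controlled
    between- and within-individual variation so every stage is testable
    without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
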