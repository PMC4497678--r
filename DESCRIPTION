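Package: zipflemma
Title: Zipf's Law Tail Fitting for Word-Form and Lemma Frequency Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying Zipf's law in type-frequency distributions of
    annotated text, comparing word forms with their lemmas. Reads token-per-line
    annotated corpora, builds frequency tables under several unit definitions,
    fits discrete power-law tails by Hurwitz-zeta maximum likelihood with
    automatic lower-cutoff selection via Monte-Carlo Kolmogorov-Smirnov
    goodness-of-fit, computes frequency spectra and their finite-size rescaling
    collapse, and runs a cross-text statistical battery (exact sign-flip tests,
    permutation correlation tests, simulated-null paired t tests, mean
    independence regressions). Includes a seeded broken-stick synthetic corpus
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
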