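Package: cooid
Title: Vocal Individuality Analysis for Harmonic Contact Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying vocal individuality in harmonic, weakly
    frequency-modulated contact calls such as the coo calls of golden
    snub-nosed monkeys. Provides a source-filter call synthesizer with
    controllable within- and between-individual variation, extraction of
    fourteen standard acoustic parameters (duration, fundamental-frequency
    statistics, harmonics-to-noise ratio, the first four formants and
    formant dispersion), corrected coefficients of variation and the
    potential for individual identity coding (PIC), nonparametric
    inter-individual screening (Kruskal-Wallis and pairwise Mann-Whitney
    tests with Bonferroni adjustment), and principal component analysis
    followed by prior-adjusted discriminant function analysis with
    leave-one-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
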