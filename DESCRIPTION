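Package: nmrTreeRank
Title: Assignment-Free Benchmarking of 1H NMR Chemical-Shift Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarks proton NMR chemical-shift predictors without
    assigned spectra. Predicted shift/coupling lists are turned into
    simulated 1D spectra by a first-order multiplet model, compared to
    experimental spectra with a recursive tree similarity (or a classical
    binning cosine baseline), and scored by Mean Reciprocal Rank,
    cumulative correct-match curves and an absolute/relative
    prediction-accuracy decomposition of the correct-match versus
    best-match similarity plane. Includes JCAMP-DX and matrix spectrum
    input/output, a seeded synthetic-data generator for end-to-end
    validation, and the traditional assigned shift-error histogram for
    cross-checking both evaluation routes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
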