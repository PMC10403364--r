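Package: stereosmell
Title: Bilateral Pheromone Sensing: Distance Tuning, Angular Decoding and
    Circuit Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for how flies localize a conspecific from
    bilateral pheromone signals. Provides a forward model of
    distance-dependent olfactory responses with contralateral inhibition,
    calcium-trace preprocessing (dF/F0, Butterworth smoothing, per-ROI
    normalization, response statistics), four-parameter logistic
    distance-tuning fits (ED50, RSE), stimulus-response cross-correlation
    lags, a positive-derivative model of looming-selective responses,
    hexagonal-lattice spatial coding with sine/cosine regressions and a
    bivariate linear position decoder, behavioral spatial statistics
    (opposite-sex preference, turn detection with circular statistics,
    treadmill lateral displacement with permutation tests), and
    connectome synapse-table analyses (partner selection, input
    selectivity, contra/ipsi bias, cable fractions, Ward clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
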