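Package: vocnet
Title: Ensemble Neural Decoding of a Vocal Repertoire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how small ensembles of auditory
    neurons encode a categorical vocal repertoire. Provides a synthetic
    generator of call-type-structured vocalizations and tuned spiking units,
    Gaussian-window spectrograms and modulation power spectra (MPS),
    bioacoustic feature extraction, neural response featurization (response
    strength Z and temporal principal components), Gaussian naive-Bayes
    ensemble decoding with leave-one-exemplar cross-validation, modulation
    receptive fields projected into a Fisher discriminant space with a
    volume-spanned tuning metric, dendrogram-cut comparisons via the
    adjusted Rand index, and ensemble-corrected statistics (effective
    sample size, corrected SEM, F and t tests) for overlapping ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    e1071,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
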