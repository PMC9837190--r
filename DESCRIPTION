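Package: popvision
Title: Decoding Character Presence from Human Single-Unit Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for decoding the visual presence of movie
    characters from windowed population spike data. Provides a synthetic-data
    generator that emulates the statistical structure of intracranial
    single-unit recordings during continuous movie viewing (character
    timelines with cuts, scenes and dialogue ambiguity; Poisson spiking with
    character-tuned gain and controllable within-region correlation; a
    clip-recognition memory session), spike-train preprocessing (rate
    filtering, artifact-bin detection, binning and resampling),
    Yes/No/Do-Not-Know frame labelling and window construction, LSTM and CNN
    decoders trained with a DNK-masked Kullback-Leibler loss under 5-fold
    cross-validation, region and electrode knockout importance with a synergy
    statistic and exact binomial summaries, memory-test analyses (activation
    GLM, association versus coactivation conditional probabilities, phase
    comparison), and semi-supervised identity clustering of track embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    e1071,
    glmnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
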