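Package: gpcircuit
Title: Class and Intensity Inference in a Gamma-Poisson Generative Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic modelling of sensory stimuli whose class and
    intensity are statistically dependent. Implements a Gamma-Poisson
    generative model with closed-form posteriors over stimulus class and
    intensity, a two-layer soft winner-take-all circuit approximation of
    that inference, online Hebbian and intrinsic-plasticity learning rules
    with a batch expectation-maximization reference sharing the same fixed
    points, four contrastive-stress estimators with a root-mean-square
    comparison protocol, a semi-supervised Bayesian read-out classifier,
    and synthetic-data generators (rectangle images, digit-like images
    with class-correlated brightness, logatome-like spectrograms) together
    with the associated preprocessing transforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
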