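Package: pdeconf
Title: Signal-Detection Models of Confidence and Post-Decision Evidence Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative signal-detection models of perceptual choice and
    confidence with post-decision evidence integration, including temporal
    weighting, choice weighting and choice bias variants. Provides a
    synthetic-data generator emulating a dot-density discrimination study
    (2-down-1-up calibration staircase, a 60-trial confidence task and a
    120-trial post-decision evidence task) over a population with planted
    radicalism structure; per-subject metacognition metrics (d-prime,
    maximum-likelihood meta-d-prime, confidence bias, quadratic-scoring-rule
    earnings); per-subject evidence-integration regressions; MAP model
    fitting by quadrature marginalization of latent internal samples; and a
    group-level statistical battery (robust bisquare regressions, variance
    inflation factors, BIC model comparison and posterior-predictive
    simulation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
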