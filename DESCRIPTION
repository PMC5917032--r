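Package: asrdemog
Title: Two-Sex Demographic Analysis of Adult Sex Ratio Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the adult sex ratio (ASR) of stage-structured
    populations from individual mark-recapture and breeding data. Implements
    Cormack-Jolly-Seber maximum-likelihood estimation of sex- and stage-specific
    apparent survival with AICc model selection, a nonlinear two-sex projection
    matrix with a harmonic-mean mating function, derivation of ASR from the
    stable stage distribution, life table response experiment (LTRE)
    decomposition of ASR bias into vital-rate contributions, bootstrap
    propagation of mark-recapture uncertainty into ASR, multinomial
    simultaneous confidence intervals for parental-care proportions, and
    bootstrap regressions of parental cooperation on ASR. Includes a synthetic
    data generator so the full pipeline can be exercised and validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
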