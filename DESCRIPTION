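Package: scrAFT
Title: Bayesian Accelerated Failure Time Illness-Death Models for
    Semi-Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian accelerated failure time (AFT) illness-death
    models to semi-competing risks data, where a terminal event (death)
    can censor a non-terminal event (disease recurrence) but not the
    reverse. Three transition-specific log-linear regressions (recurrence,
    death without recurrence, and the post-recurrence sojourn to death)
    share a normally distributed subject-level frailty. Baseline error
    distributions are either log-normal or truncated Dirichlet process
    mixtures of normals, sampled by a fully conjugate Gibbs scheme with
    data augmentation. Includes model comparison by DIC and LPML,
    time-ratio reporting with credible intervals, model-based adjusted
    survival curves, Kaplan-Meier / log-rank descriptive summaries, and a
    ground-truth synthetic cohort generator emulating a colorectal-cancer
    surgical cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
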