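Package: resilmet
Title: Serum Metabolomics of Cognitive Resilience
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking untargeted LC-MS serum metabolomics to
    longitudinal cognitive resilience. Computes per-participant resilience
    scores as deviations of person-specific cognitive-decline slopes from the
    cohort slope (linear mixed model BLUPs), conditions feature tables for
    compositional analysis (dead-volume, blank and sparsity filters, robust
    centered log-ratio transform, covariate residualization, age-harmonizing
    visit selection), fits one-component sparse partial least squares
    regression with cross-validated stability, permutation testing and
    external validation, runs two-step hurdle and per-feature age mixed
    models with Benjamini-Hochberg correction, and provides tandem-MS query
    operators (neutral loss, shared fragments, co-occurrence, retention-time
    precedence, delta-mass annotation). Includes a fully labeled synthetic
    cohort generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
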