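Package: octnorms
Title: Bilateral Macular Thickness Models, Confounder Sensitivity and
    Meta-Analysis for Cross-Population OCT Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-population studies of macular retinal and
    choroidal thickness measured on the ETDRS grid by optical coherence
    tomography. Provides a data model and deterministic CSV round-trip for
    per-eye sector measurements, a synthetic-cohort generator with
    subject-level random effects inducing realistic inter-eye correlation,
    per-sector random-intercept mixed models estimated by restricted
    maximum likelihood with Bonferroni-adjusted Wald inference, a Monte
    Carlo sensitivity analysis quantifying how large an
    unmeasured-confounder measurement error may grow before an ethnicity
    association loses significance, DerSimonian-Laird random-effects
    meta-analysis with Cochran's Q and I-squared heterogeneity metrics and
    age-group stratification, analytic noncentral-F and simulation-based
    power analysis, and a seeded end-to-end pipeline with a reproducible
    results manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    metafor
Config/testthat/edition: 3
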