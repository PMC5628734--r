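Package: hkmeta
Title: Hartung-Knapp Random-Effects Meta-Analysis, Dataset Taxonomy, and
    Analysis Conventions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Random-effects meta-analysis with the Hartung-Knapp (Knapp-Hartung,
    Sidik-Jonkman) small-sample modification. Provides three between-study
    variance estimators (DerSimonian-Laird, restricted maximum likelihood, and
    Paule-Mandel), the generalized heterogeneity statistic H*, standard,
    modified, constrained-modified and common-effect confidence intervals, a
    taxonomy that classifies meta-analysis datasets into the seven observable
    groups defined by four binary outcomes, six conventions for choosing which
    analysis to present, and a simulation harness for taxonomy-group frequency
    surveys, impossibility audits and coverage studies. Binary-outcome 2x2
    tables are converted to log odds ratios with a continuity correction. A
    command-line interface exposes the analysis, classification and simulation
    pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
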