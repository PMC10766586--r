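Package: taxassoc
Title: Ensemble Feature Selection Linking Microbial Taxa to Continuous Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies features of a microbial community data matrix (ASV/OTU
    counts or counts aggregated at a higher taxonomic rank) associated with a
    continuous per-sample variable such as thermal tolerance (ED50). Runs an
    ensemble of eight model paths (l1 and centered log-ratio normalization
    crossed with lasso, adaptive lasso, correlation-based feature selection,
    and the full feature set), validates every path by leave-one-out
    cross-validation with random-forest regression, and aggregates feature
    importances, model performance and selection robustness into a single
    per-feature score in [0,1]. Includes a synthetic compositional data
    generator with planted associations, repeat-run stability and jackknife
    sensitivity protocols, and a two-tier (family-then-ASV) workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    ranger,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
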