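Package: bridgelearn
Title: Similarity-Controlled Pseudoword Learning: Stimulus Design, Scoring,
    Simulation, and Mixed-Model Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for two-session bridge/terminus pseudoword
    learning experiments. Builds orthotactic bigram and phonotactic biphone
    probability models from a reference lexicon, scores pseudoword candidates on
    a composite z-transformed English-similarity metric with percentile
    thresholds, generates CVCVC stimulus lists with onset balancing and
    substitution-neighbor (bridge/terminus) structure under covariate-matching
    constraints, scores typed responses with positional partial credit,
    categorizes terminus items by bridge-word knowledge, simulates synthetic
    participant data with the experiment's random-effect structure, and runs
    linear mixed-effects inference (REML, Satterthwaite degrees of freedom,
    Tukey-corrected marginal-means contrasts) together with Monte-Carlo power
    analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
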