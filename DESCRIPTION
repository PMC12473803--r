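Package: tugcop
Title: Center-of-Pressure Feature Analysis of Instrumented Timed Up and Go Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for insole-derived center-of-pressure (CoP)
    recordings collected during the Timed Up and Go (TUG) test. Computes CoP
    from raw plantar pressure sensor frames, extracts a 72-feature multi-domain
    sway descriptor set per foot (positional, dynamic, frequency and stochastic
    families, including stabilogram diffusion analysis), aggregates left and
    right feet into 144 bilateral average and asymmetry features, builds
    group-wise kernel-density CoP occupancy maps, and benchmarks five
    classifiers for Parkinson's disease detection under a fixed protocol:
    participant-level 80/20 split, per-model sequential forward selection with
    5-fold inner cross-validation scored by F1, and a single held-out
    evaluation. Includes a seeded synthetic two-foot TUG CoP generator so the
    full pipeline is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    MASS,
    e1071,
    randomForest,
    class,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    jsonlite,
    optparse
Config/testthat/edition: 3
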