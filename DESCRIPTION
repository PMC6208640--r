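Package: cocultr
Title: Predicting Microbial Coculture Outcomes and Interaction Mechanisms
    from Binary Trait Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represents pairwise microbial coculture experiments as
    concatenated binary trait vectors (responder first, partner second) and
    classifies interaction outcomes with a random forest whose per-node class
    counts are retained, so that per-sample feature contributions can be
    decomposed along decision paths. Net feature contributions rank candidate
    interaction mechanisms (contended or cross-fed metabolites), and the
    expected cost of random mechanism queries provides the analytic baseline.
    Includes a toy batch dynamic flux balance analysis (dFBA) simulator over
    small stoichiometric models that generates labeled synthetic communities
    with known competition and cross-feeding mechanisms, plus evaluation
    protocols: out-of-bag metrics, ROC/AUC, permutation variable importance,
    paired learning curves, community-size sweeps, and balanced-subsample
    training for rare classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pROC,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    pracma,
    randomForest,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
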