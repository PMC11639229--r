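Package: ligandAL
Title: Active-Learning Campaigns for Ligand Activity Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Framework for iterative active-learning campaigns over
    time-stamped structure-activity data in lead optimization. Provides S4
    containers for fingerprinted compound sets, a pluggable surrogate
    affinity predictor (similarity-kernel and additive-on-bits baselines)
    with per-candidate novelty and nearest-neighbor diagnostics,
    dual-criterion batch acquisition (predicted-active among the
    best-covered, plus maximally informative), probabilistic multi-metric
    model selection, campaign evaluation statistics (Kendall tau, mean
    unsigned error, bootstrap confidence intervals, kcal/mol error bins,
    goal-compound rank), and a calibrated synthetic structure-activity
    landscape generator for benchmarking the whole loop end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
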