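Package: chemrank
Title: Ordered Prediction of Drug Indications from Chemical-Chemical
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Guilt-by-association ranking of candidate indications for drug
    compounds. Each query drug is scored against a labelled training set by
    summing the confidence scores of its chemical-chemical interactions
    (STITCH detailed-links dialect) per indication category, yielding a full
    ordered list of candidate indications. A comparator based on cosine
    similarity of molecular-descriptor vectors, a jackknife (leave-one-out)
    evaluation harness with ordered-accuracy, per-category accuracy, coverage
    and precision/recall statistics, two randomisation null controls, and a
    synthetic homophilous-network data generator are included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
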