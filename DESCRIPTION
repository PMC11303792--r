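Package: rareRules
Title: Frequent and Rare Association Rule Mining with Unexpected-Rule Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines frequent and rare association rules from boolean
    transaction encodings of clinical records and isolates "interesting"
    rare rules: rare disease-predicting rules whose antecedents are highly
    similar (Jaccard) to frequent health-predicting rules but whose
    consequents contradict them, attributing each to the trigger factor
    that flips the outcome. Provides FP-growth pattern mining over a
    frequent band (support >= minSup) and a rare band
    (minRare <= support < minSup), exhaustive antecedent/consequent rule
    enumeration with support, confidence, lift, leverage and conviction,
    strong-rule filtering, class-consequent rule typing, Jaccard-based
    matching of rare against frequent rules, a deterministic planted-itemset
    synthetic transaction generator, and a pipeline driver with structured
    run reports. Includes discretization and one-hot transaction encoding
    for a combined multi-source heart-disease records table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
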