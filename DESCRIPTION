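Package: mitosleep
Title: Quantification Pipelines for Drosophila Sleep and Mitochondrial
    Metabolism Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested quantification stack for fly sleep-metabolism
    studies: ratiometric mitochondrial redox image scoring with outlier and
    background gating, lipid-droplet segmentation and morphometry via
    triangle and Renyi-entropy auto-thresholding, a windowed mitophagy
    colocalization index, TriKinetics DAM sleep architecture metrics with
    control subtraction and error propagation, Seahorse-style oxygen
    consumption rate quality control, a normality-gated group-comparison
    policy with a dual-control conservative-P rule, delta-delta-Ct
    expression quantification, and ground-truthed synthetic-data generators
    for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
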