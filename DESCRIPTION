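Package: deepMRE
Title: Two-Layer Deep Learning Framework for microRNA Target Prediction
Version: 0.1.0
Authors@R:
    person("deepMRE", "Developers", email = "deepmre@example.org",
           role = c("aut", "cre"))
Description: Predicts microRNA (miRNA) targets with a two-layer architecture.
    The first layer enumerates candidate miRNA response elements (MREs) of
    canonical (6mer to 9mer), centered and 3' compensatory site categories in
    3' UTR and CDS regions, encodes each site as five feature channels
    (extended MRE sequence, miRNA-MRE chimera, thermodynamic duplex structure,
    RNA folding context, and per-base conservation), and scores sites with a
    five-branch convolutional-recurrent (CNN-GRU) network trained per region.
    The second layer aggregates per-region maximum MRE scores per
    miRNA-gene interaction and classifies interactions with a
    gradient-boosted tree meta-learner. Includes training-set construction
    rules for AGO-CLIP peaks, perturbation expression tables and CLASH
    chimeras, a self-contained synthetic-data generator, evaluation metrics
    (ROC/PR, Youden thresholds, rank-based functional-efficacy tests) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    IRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
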