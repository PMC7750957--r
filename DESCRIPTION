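Package: swisol
Title: Solubility-Weighted Index for Recombinant Protein Solubility Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-only prediction of recombinant protein solubility in
    Escherichia coli via the Solubility-Weighted Index (SWI), the arithmetic
    mean of optimized per-residue weights derived from normalized crystallographic
    B-factors. Provides flexibility profiles and global flexibility from
    sliding-window averaged normalized B-factors, Kyte-Doolittle GRAVY, logistic
    calibration of SWI to a probability of solubility, the full weight-training
    pipeline (homology-aware cross-validation folds, class-balanced bootstrap
    resampling, derivative-free AUC maximization, weight averaging), per-residue
    enrichment bit scores against a background set, simulated-annealing expansion
    of sequence regions to maximize solubility, solubility-tag fusion scoring, a
    synthetic labeled-dataset generator with planted weights for end-to-end
    validation, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    optparse,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
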