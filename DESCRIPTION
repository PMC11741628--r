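Package: ikirmod
Title: Inhibitory KIR Modification of HLA Class II Disease Associations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how inhibitory killer-cell
    immunoglobulin-like receptor (iKIR) gene dosage modifies HLA class II
    disease associations in type 1 diabetes. Implements iKIR ligand
    assignment and the weighted functional-iKIR score, stratified and
    interaction logistic association analysis, score-permutation tests with
    a frequency-weighted multi-genotype statistic, an exhaustive pairwise
    driver-genotype screen with effective-number-of-tests correction, a
    stratified family transmission (TDT-style) analysis, population impact
    estimates (prevented fraction, normalized-score odds ratio), and an ODE
    model of regulatory-T-cell-mediated beta-cell destruction. Ships a
    synthetic cohort and trio generator so the whole pipeline is testable
    without access to the original genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
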