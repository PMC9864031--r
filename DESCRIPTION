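Package: mbgem
Title: Constraint-Based Metabolic Modelling of Medulloblastoma Versus
    Healthy Cerebellum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scale metabolic analysis of medulloblastoma against a
    healthy cerebellum reference: model structures with gene-protein-reaction
    (GPR) boolean logic and SBML/JSON input-output, flux balance analysis (FBA)
    and minimization-of-metabolic-adjustment (MOMA) solving, GIMME-style
    transcriptome integration, artificially-centered hit-and-run (ACHR) flux
    sampling with Welch/Benjamini-Hochberg differential-flux testing,
    ZF/ZG transcriptional-regulation classification, flux coupling analysis
    against the growth reaction, single and double gene deletion screens with
    a healthy-cell safety filter, and a Tanimoto-similarity antimetabolite
    screen with competitive-inhibition simulation. Ships generators for a
    synthetic two-cell (neuron/astrocyte) cerebellum model and series-matrix
    style expression data with planted differential signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    jsonlite,
    Matrix,
    quadprog,
    Rcpp,
    rlang,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
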