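Package: fluxfit
Title: Flux Coupling and Pooled Mutant Fitness Integration for
    Genome-Scale Metabolic Models
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based analysis of genome-scale metabolic models
    driven by pooled barcoded transposon mutant fitness data. Provides
    model input/output (SBML Level 3 fbc and a tabular dialect), flux
    balance and flux variability analysis, in-silico gene essentiality
    screens, confusion-table comparison of predicted essentiality
    against pooled fitness phenotypes with error-minimising cutoff
    selection, flux coupling analysis with sink augmentation and
    condition-dependent re-coupling, resampling-calibrated cofitness
    statistics for metabolic module validation and orphan-gene
    discovery, minimal-additions gap filling, and conditional
    essentiality designs for selection-based gene identification.
    Includes a synthetic-data generator producing toy networks with
    planted coupling structure and simulated fitness matrices for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Metabolomics, Network, Software, SystemsBiology
RoxygenNote: 7.3.3
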