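Package: qstfst
Title: Q_ST-F_ST Comparison and SSR Population Genetics for
    Common-Garden Provenance Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for half-sib common-garden provenance
    trials genotyped at codominant microsatellite (SSR) loci. Computes
    per-population diversity statistics (Na, Ne, Ho, He, Nei gene
    diversity, Shannon index, PIC, F_IS), Hardy-Weinberg exact tests
    with Bonferroni control, Nei-Chesser G_ST, multilocus
    Weir-Cockerham F_ST, and Nei (1972) genetic distances with
    neighbor-joining trees and locus-bootstrap support. Fits the
    randomized-block half-sib mixed model by REML to extract provenance
    and family variance components, forms global and pairwise Q_ST, and
    tests each trait against neutral expectation by resampling the null
    distribution of Q_ST - F_ST. Includes Mantel tests, linearized
    isolation-by-distance regression, spherical chord distances with
    elevation, climate distance matrices, Evanno delta-K model
    selection, and an island-model (Balding-Nichols) simulator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
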