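Package: cyclofit
Title: Kinetic Analysis of Chymotrypsin-Coupled Peptidyl-Prolyl Isomerase Assays
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the chymotrypsin-coupled spectrophotometric assay of
    peptidyl-prolyl cis-trans isomerase (PPIase, cyclophilin) activity:
    mechanistic simulation of absorbance progress curves, first-order
    rate-constant fitting, catalytic-efficiency and specific-activity
    computation, tight-binding inhibition modelling (Morrison equation) with
    Henderson-plot inhibition-constant estimation for cyclosporin A and
    Cu2+ titrations, and a sliding-window hydrophobic-moment scanner for
    delineating amphiphilic calmodulin-binding helices. Includes seeded
    synthetic-data generators emulating the assay regime of the Arabidopsis
    cyclophilin AtCyp19-3 so that the whole pipeline can be exercised
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Matrix,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
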