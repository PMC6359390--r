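Package: fqsar
Title: 2D-QSAR Modelling of Fluoroquinolone Immunoassay Cross-Reactivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to model the cross-reactivity of fluoroquinolone
    antibiotics in competitive immunoassays from 2D molecular structure.
    Computes graph-based descriptors (methantriyl group counts, Kier-Hall
    electro-topological state sums, tetrahedral stereocentre counts) and
    van-der-Waals shadow projection areas, converts IC50 ratios to
    cross-reactivities with explicit handling of left-censored entries,
    selects multiple linear regression models by genetic function
    approximation with the Friedman lack-of-fit score, and validates them
    by leave-one-out and leave-many-out cross-validation and external
    test-set prediction. Ships measured cross-reactivity and descriptor
    tables for 26 quinolones against anti-ciprofloxacin and
    anti-clinafloxacin antibodies, and a synthetic data generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    ChemmineR
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
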