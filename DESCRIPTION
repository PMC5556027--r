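Package: frackill
Title: Dynamical Modelling of Cisplatin-Induced Fractional Killing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hybrid ordinary-differential-equation model of fractional
    killing in cisplatin-treated tumour cells. Couples a generic-formula
    description of p53/Mdm2 dynamics to a mass-action module of apoptosis
    initiation (BH3/BCL/BAX) under an incoherent feedforward loop in which
    the drug both activates p53 and induces the Caspase8 inhibitor CIAP.
    Provides seeded heterogeneous virtual-cell populations, cell-fate
    classification, one- and two-parameter saddle-node (threshold)
    analysis of the apoptosis switch, trajectory overlays on the
    (p53, CIAP) control plane, and classification of anti-fractional-
    killing interventions into three dynamical categories (bifurcation
    geometry, cellular trajectory, or both).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
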