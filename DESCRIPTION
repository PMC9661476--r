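Package: ttrstab
Title: Quantitative Analysis of Transthyretin Kinetic Stabilizers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for the in silico and in vitro characterization of
    small-molecule transthyretin (TTR) kinetic stabilizers. Implements
    molecular-dynamics binding-energy bookkeeping and hydrogen/halogen-bond
    contact statistics, a two-site ligand-binding model for isothermal
    titration calorimetry (equilibrium solving, thermogram simulation and
    nonlinear fitting, with and without cooperativity), urea-induced tetramer
    dissociation kinetics, acid-mediated aggregation and cell-viability assay
    statistics, plasma densitometry metrics (isoelectric-focusing tetramer
    stabilization, thyroxine binding competition) and solubility averaging.
    Seeded synthetic-data generators emulate each assay so the full pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    knitr
Config/testthat/edition: 3
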