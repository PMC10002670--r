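Package: atlasquant
Title: Atlas-Based Registration, Quality Control and Regional Quantification of
    Histological Brain Sections
Version: 0.1.0
Authors@R:
    person("atlasquant", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying immunohistochemistry-stained features in
    serial brain section images against a labeled 3D reference atlas. Provides
    oblique atlas-plate slicing from a nine-number linear anchoring, in-plane
    nonlinear refinement driven by anchor-point deformation fields, systematic
    grid-sampling quality control of registration accuracy and section damage,
    customized collapsing of atlas ontologies into intermediate hierarchies,
    per-region stain-load quantification with connected-component object
    splitting and hemisphere masks, and downstream statistics linking regional
    loads to age effects and bulk RNA-seq gene expression. Ships deterministic
    synthetic-data generators with attached ground truth so the whole pipeline
    can be validated end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    deldir,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
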