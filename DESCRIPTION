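Package: phosphozip
Title: Phospho-Scanning Inference of Amyloid Fibril Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring the cross-beta architecture of amyloid
    fibrils from position-scanned phosphopeptide aggregation data.  Processes
    replicate thioflavin-T fluorescence kinetics (blank correction, plateau
    normalisation, interpolated half-time extraction and histogram/Gaussian
    summaries), models peptide and phosphate charge states across pH,
    constructs idealized steric-zipper coordinate models for the eight
    cross-beta symmetry classes, screens candidate strand arrangements and
    zipper classes against variant-by-pH aggregation outcomes via
    phosphosite proximity, and quantifies zipper integrity in multi-frame
    coordinate data by counting water molecules that penetrate the dry
    inter-sheet interface.  Synthetic-data generators for replicate kinetic
    curves and zipper trajectories with planted interface waters make every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    jsonlite
Config/testthat/edition: 3
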