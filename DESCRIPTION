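Package: adpcluster
Title: Clustering and Differential Analysis of Anisotropic Displacement
    Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing anisotropic atomic displacement parameters
    (ADPs) in macromolecular crystal structures refined in paired
    experimental states. Reads and writes PDB ANISOU records, computes
    per-atom tensor metrics (equivalent isotropic B-factor and anisotropy
    from the tensor eigendecomposition), summarises paired-state metric
    differences per residue and per amino-acid type with confidence
    intervals, correlates experimental displacement profiles with external
    predictions, and clusters atoms across crystals by Ward's method on the
    Euclidean distance between their paired 6-element ADP tensors. Includes
    a synthetic multi-crystal ensemble generator with planted tensor
    archetypes for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
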