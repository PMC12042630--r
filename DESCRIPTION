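Package: odontomesh
Title: 3D Tooth Mesh Classification with Recurrent Sequence Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for classifying isolated 3D tooth surface meshes into
    anatomical tooth types, for dental analysis and forensic odontology.
    Reads and writes triangular meshes (OBJ, STL, PLY), simplifies them to a
    fixed triangle budget with quadric-error-metric edge collapse, augments
    datasets with random rigid rotations and translations, encodes each mesh
    as a grayscale feature image (one row per triangle: nine vertex
    coordinates plus the triangle centroid), and classifies the image with a
    two-layer gated recurrent unit (GRU) network trained with Adam on sparse
    categorical cross-entropy. Includes LSTM, vanilla RNN and CNN baseline
    architectures, per-class precision/recall/F1 reporting, a synthetic
    parametric tooth-shape generator for fully reproducible benchmarks, and
    an end-to-end experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
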