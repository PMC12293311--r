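Package: voxdose
Title: Voxel Anthropomorphic Phantom Dosimetry and Radiography Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with voxel anthropomorphic phantoms in
    photon dosimetry and radiographic simulation. Provides a voxel
    phantom data model with plain-text fill-card input/output, a
    deterministic ray-cast kerma engine and an analog photon Monte
    Carlo engine on voxel lattices, digitally reconstructed radiograph
    projection through mesh tallies, organ absorbed-dose and
    ICRP-103 effective-dose calculation normalized per unit fluence,
    model-comparison statistics (percent differences, pairwise-complete
    RMSE, multi-model averages), a deterministic synthetic 30-organ
    body phantom generator, and XML input-deck export for lattice-based
    Monte Carlo transport codes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
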