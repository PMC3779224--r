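Package: dwiconn
Title: Connectome-Based Comparison of Diffusion MRI Encoding Schemes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates matched multi-scheme diffusion MRI acquisitions on
    known-truth fiber phantoms and carries them through a complete structural
    connectome pipeline: q-space encoding scheme construction (Cartesian
    lattice DSI, single-shell HARDI, DTI), multi-tensor signal simulation with
    Rician noise and complex averaging, orientation reconstruction (tensor
    fit, DSI Fourier/radial-projection ODF, Funk-Radon q-ball, solid-angle
    q-ball), deterministic streamline tractography, ROI connection and
    geodesic connection-distance matrices, and the comparison statistics used
    to contrast encoding schemes (normalized connectivity, fiber limitation,
    paired t-tests with Bonferroni correction, scan-rescan variability,
    distance-binned connection counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    igraph,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
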