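Package: polyhelix
Title: Geometric Assignment of Protein Helices from C-alpha Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns alpha, 3-10 and pi helices (right- and left-handed) in
    protein structures using only alpha-carbon geometry.  A helical curve is
    best-fitted to every sliding quadruple of consecutive C-alpha atoms by an
    exhaustive grid search over radius and rise combined with SVD (Kabsch)
    rigid superposition.  Per-residue helix scores measuring deviation from
    the standard alpha, 3-10 and pi helices, helix-axis bending angles, and
    two C-alpha RMSD statistics then drive a sequential pi -> 3-10 -> alpha
    assignment with merge and C-terminal extension rules.  Includes a PDB
    C-alpha reader and HELIX-record writer, a synthetic helix-trace
    generator for validation, normal-parameter calibration helpers and
    greedy RMSD clustering of assigned helices.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
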