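Package: dimerdyn
Title: Trajectory Analysis of Helix-Bundle Protein Dimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis of molecular-dynamics trajectories of two-chain
    helical-bundle proteins: backbone RMSD and stable-window detection,
    hydrogen-bond and hydrophobic-contact occupancy accounting, Kabsch-Sander
    secondary-structure assignment and helical content, a PISA-style estimator of
    dimer interface area and solvation free-energy gain with a Monte-Carlo
    P-value, and essential-dynamics principal component analysis in three
    flavours (global Cartesian, central-helix Cartesian, and inter-helix distance
    features). Includes a synthetic C2-symmetric four-helix-bundle dimer
    generator with planted concerted motions, interactions and helix unwinding
    as machine-readable ground truth, plus a rare-variant filter cascade for
    annotated exome variant tables.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
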