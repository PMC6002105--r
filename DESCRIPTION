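Package: decoysieve
Title: Kinetic Discrimination of Protein-Protein Docking Decoys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to discriminate near-native protein-protein docking
    poses from decoys by their kinetic behaviour in dynamics trajectories:
    drift classification against the starting pose, temperature-ladder
    probing of metastable traps, binding-event detection against a
    reference structure, and reference-free identification of the native
    basin through pairwise trajectory convergence. Includes an overdamped
    Langevin rigid-body simulator on designed funneled free-energy
    landscapes that generates labelled synthetic trajectories, so the
    full analysis pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
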