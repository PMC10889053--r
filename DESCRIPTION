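Package: pthl
Title: Persistent Topological Hyperdigraph Laplacians for Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structure-to-sequence featurization of 3D protein-ligand complexes
    via persistent topological hyperdigraph Laplacians. Reads protein (PDB) and
    ligand (SDF/MOL2) structures, carves out the binding region at a distance
    cutoff, builds Vietoris-Rips hyperdigraphs over a filtration, computes
    combinatorial and persistent Laplacian spectra and Betti numbers, and embeds
    element-specific spectral summaries into fixed-shape topological sequences
    (filtration steps x 143 element combinations x 6 statistics). Also provides
    a compact transformer (masked reconstruction pretraining, affinity
    regression fine-tuning, attention scores, gradient saliency), CASF-style
    scoring, ranking, docking and screening metrics with consensus averaging,
    and seeded synthetic-data generators so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
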