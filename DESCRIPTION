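Package: potentialbind
Title: Protein-Ligand Binding Affinity from Frame-Averaged Atomic Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-ligand binding affinity as the summed per-atom
    energy difference between the bound complex and its unbound components.
    Atomic point clouds parsed from PDB and SDF/MOL2 files are cropped to the
    binding pocket, turned into radius graphs, and encoded with an
    SE(3)-invariant frame-averaged message-passing network whose output head
    assigns an energy to every atom. Includes a balanced mean-squared-error
    regression loss for skewed affinity labels, a differentiable ranking loss
    based on approximate NDCG, an AdamW training loop with linear warm-up and
    cosine annealing, a synthetic complex generator with an additive pairwise
    oracle potential for end-to-end validation, and per-atom contribution
    export for inspection in molecular viewers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
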