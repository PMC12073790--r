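Package: goldsam
Title: Construction and Trajectory Analysis of Peptide Self-Assembled
    Monolayers on Gold Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds model gold-slab monolayers of linker-conjugated
    peptides (hexagonal gold layer, grafted conjugates, formal-charge and
    counterion bookkeeping), generates desk-scale Brownian-dynamics
    trajectories of grafted bead chains with tunable inter-chain
    attraction and a rigid protein-like probe, and analyses slab
    trajectories the way protein-adsorption MD studies do: per-moiety
    mass-density profiles along the surface normal, rational
    switching-function contact scores, close-contact counts and
    residue-level contact persistence maps, Shrake-Rupley solvent
    accessible surface area with water-sized and protein-sized probes,
    height-map surface morphology with pocket detection, and a
    constant-force tensile deformability metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
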