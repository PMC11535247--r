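Package: mrtvasc
Title: Multiscale Simulation of Microbeam Radiotherapy Acting on Brain
    Microvasculature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Cellular-Potts (Glazier-Graner-Hogeweg) simulation of normal and
    tumor-remodeled brain capillary networks under microbeam radiation therapy
    (MRT). Provides a voxel-lattice cell engine with adhesion, volume,
    elongation and chemotaxis energies; a synthetic capillary-network
    generator with clustering of capillary voxels into elongated vascular
    cells and VEGF-driven remodeling; avascular tumor growth with
    oxygen-dependent proliferation; a dual-field oxygen model in which
    vascular pO2 diffuses only through capillaries between clamped donor and
    acceptor boundaries while cellular pO2 diffuses tissue-wide with periodic
    boundaries and Michaelis-Menten uptake; a parametric peak/valley microbeam
    dose model; stochastic endothelial dose-response killing with
    deterministic beam-path ablation; and outcome scoring (hypoxia, necrosis,
    perfusion loss, spatial uniformity of the vasculature).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
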