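Package: fibrilstab
Title: Solvation Stability Maps, Density Occupancy and Interface Metrics
    for Amyloid Fibril Structures
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative structural analysis of amyloid fibrils and their
    bound small-molecule disaggregants. Implements per-atom solvation
    free-energy stability maps of fibril chains (Shrake-Rupley solvent
    accessible surface areas scaled by atomic solvation parameters, with a
    per-residue ordering-entropy term) and pairwise difference maps; cryoEM
    density-map handling with three-mask ligand occupancy estimation and
    masked real-space model-map correlation; ligand-site interface metrics
    (buried surface area, hydrogen-bond geometry, ring-stacking and
    stack-curvature profiles, multi-pose comparison); per-residue
    inter-layer spacing profiles for single models and coordinate
    ensembles; and z-score consensus ranking of virtual-screen docking
    tables. A synthetic-fixture generator builds helically stacked
    two-protofilament fibrils, inter-protofilament ligand columns and
    Gaussian-atom density maps with known ground truth so every analysis is
    testable without deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: StructuralBiology, Proteomics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'density.R'
    'fixtures.R'
    'interface.R'
    'peptide-build.R'
    'sasa.R'
    'screen.R'
    'solvation.R'
    'spacing.R'
    'structure-io.R'
    'symmetry.R'
    'utils-geometry.R'
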