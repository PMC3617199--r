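Package: resistmap
Title: Per-Residue Backbone Resistance Mapping by Steered-Dynamics Surface Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps the mechanical compliance of a protein surface by pulling
    each surface-exposed residue's C-alpha atom with a moving harmonic spring
    and regressing spring force against dummy-atom displacement; the slope is
    the residue's resistance coefficient (pN/Angstrom). Provides
    solvent-accessible surface area selection of surface residues, pulling
    geometry construction, a Langevin dynamics engine with in-repo harmonic
    and elastic-network force fields (plus an adapter contract for external
    all-atom engines), replicate aggregation, stability-patch detection,
    conformation-pair delta analysis, equilibrium-fluctuation RMSD profiles
    and their correlation with resistance, and in silico alanine-scan
    mutagenesis with t-test comparison against wild type. Includes synthetic
    bead and helix fixture generators with analytically known stiffness so
    the full protocol is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
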