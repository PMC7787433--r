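Package: idrocc
Title: Ensemble Occupancy Analysis of Intrinsically Disordered Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generates sterically feasible conformer ensembles for
    intrinsically disordered regions (IDRs) with an excluded-volume
    Monte-Carlo chain builder, docks a rigid ligand at short linear motifs
    by least-squares superposition with van der Waals clash filtering,
    infers which conformers can hold several ligands simultaneously from
    single and pairwise docking feasibility, and quantifies
    binding-induced expansion (radius of gyration, end-to-end distance,
    energy-dimension quadrants) and motif co-accessibility (hypergeometric
    enrichment, mutual information) across the ensemble. Includes
    charge-patterning sequence descriptors (kappa, omega) and motif/linker
    characterization for multivalent IDRs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    bio3d,
    jsonlite,
    digest,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
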