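Package: mhc2struct
Title: Structure-Based Ab Initio Prediction of Peptide Binding to MHC Class II
Version: 1.0.0
Authors@R:
    person("mhc2struct", "developers", email = "mhc2struct@example.org",
           role = c("aut", "cre"))
Description: Structure-based ("ab initio") predictors of peptide binding to
    MHC class II molecules that require no peptide:MHC binding data: a
    distance-dependent statistical pair potential derived from reduced
    (centroid) representations of protein structures, a position-specific
    scoring matrix (PSSM) derived from atomic contact maps of peptide:MHC
    complexes, and scanning of peptides for the best-scoring 9-mer binding
    core against any 20x9 matrix, including packaged contact-map and
    molecular-dynamics derived matrices for HLA-DRB1*0101. Includes PDB
    structure handling (parsing, residue centroids, rigid-body superposition,
    RMSD/RMSF trajectory utilities), IC50-based binder classification,
    ROC/AUC evaluation with the Hanley-McNeil standard error, and seeded
    synthetic-structure generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
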