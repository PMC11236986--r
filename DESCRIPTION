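Package: chemtriage
Title: Ligand Library Triage and Protein-Ligand Interaction Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling and evaluating target-focused small-molecule
    libraries, developed around the tissue transglutaminase (TG2) inhibitor
    discovery workflow. Provides circular (Morgan-type) fingerprints with
    Tanimoto similarity, Butina sphere-exclusion clustering, Bemis-Murcko
    scaffold decomposition and frequency mining, PAINS/rule-of-five triage,
    IC50-to-binding-free-energy conversion with ligand-efficiency and
    group-outlier statistics, geometric profiling of protein-ligand complexes
    (close contacts, pi-stacking classification, cavity occupancy, Kabsch
    superposition, catalytic-residue deviations), alanine masking of multiple
    sequence alignments for conformation-biased structure prediction, ingestion
    of docking result tables, and seeded synthetic-data generators that provide
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
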