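Package: netcombo
Title: Network-Based Screening of Drug Combinations on the Human Interactome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies drug-drug target module separation and drug-disease
    network proximity on a protein-protein interactome, classifies
    drug-drug-disease triples into six topological exposure classes, and ranks
    Complementary-Exposure pairs as candidate efficacious combinations.
    Includes degree-preserving randomization z-scores, four alternative
    set-to-set network distances, five pharmacological similarity metrics
    (chemical fingerprint, target sequence, co-expression, Gene Ontology,
    ATC clinical), target-overlap statistics, balanced-resampling ROC/AUC
    evaluation, permutation tests, and deterministic synthetic fixture
    generators so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
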