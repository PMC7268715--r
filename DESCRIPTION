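Package: cas16s
Title: Design of Host-Specific CRISPR-Cas9 Guides for 16S rRNA Amplicon
    Host Depletion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing Cas9 guide RNAs that cleave host organelle
    (mitochondrial and plastid) 16S rRNA gene amplicons during two-step PCR
    library construction, so that bacterial reads dominate 16S amplicon
    sequencing of plant-associated microbiota. Enumerates Cas9-targetable
    protospacers (20-mer + NGG) on host 16S genes, screens them against a
    prokaryotic 16S reference set using anchored global alignment with
    seed-region and PAM-class (NGG/NAG) edit ceilings, ranks guide
    specificity by off-target counts, intersects guides with in-silico PCR
    amplicons from degenerate universal primers, and simulates Cas9
    digestion of mock amplicon communities. Includes a seedable synthetic
    data generator that plants near-match off-target sites at controlled
    edit counts and positions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
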