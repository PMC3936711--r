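Package: casforge
Title: CRISPR-Cas Locus Discovery by Similarity Seeding and Genomic-Neighborhood Recruitment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for discovering cas (CRISPR-associated)
    genes in complete genomes, draft genomes and metagenome assemblies.
    Confident similarity hits against known Cas protein families seed loci
    that are expanded by iterative recruitment of weakly similar genes within
    a three-gene neighborhood; assembled loci are classified into CRISPR-Cas
    types and subtypes by signature genes; unannotated genes inside loci are
    clustered with Markov clustering (MCL) into candidate novel Cas families;
    per-family scoring profiles are refined by recruit-above-worst-seed
    iteration with gathering/trusted/noise cutoffs; and cas-gene abundance is
    compared across body habitats with paired tests. A synthetic-data module
    generates replicons with planted loci of known type and subtype, decoy
    hits, toxin-antitoxin insertions and a multi-habitat cohort so that every
    stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
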