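Package: txwb
Title: Transcriptome Workbench for De Novo Annotation, Expression and Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable workbench for de novo transcriptome projects
    without a reference genome. A single-project path takes transcript (or
    protein) FASTA files and per-library read counts and computes GC content,
    open reading frames, RPKM normalisation, the Poisson-based R statistic
    for library heterogeneity, binomial SNP calls from pileup columns, and
    BLAST-tabular annotation joined to UniProt-style flat-file records and a
    GO ontology. A multi-project path merges several projects, filters
    redundant sequences, clusters by transitive closure of self-BLAST
    similarity (or imports external cluster sets such as orthoMCL groups),
    and assigns majority annotations to clusters. All results live in a
    plain-text project store with a filter/query layer, CSV/FASTA/correlation
    exports, and a seeded synthetic-fixture generator for every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
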