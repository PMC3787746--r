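Package: omegascan
Title: Molecular Evolution and Polymorphism Analysis for De Novo Avian
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for comparative molecular-evolution analysis
    of de novo songbird brain transcriptomes against an annotated relative:
    k-mer-seeded ortholog assignment with Karlin-Altschul e-value filtering,
    codon-aware alignment refinement from fragmented transcripts (frame
    repair, per-species consensus, CDS-guided trimming), Nei-Gojobori (NG86)
    counting and Goldman-Yang (GY94) maximum-likelihood estimation of dN/dS,
    three-taxon branch-model likelihood-ratio tests with false-discovery-rate
    control, bootstrap-concatenation estimates of genome-wide omega,
    reference-free heterozygous SNP discovery from single-individual reads
    with chromosomal mapping and compartment classification, and downstream
    term-enrichment and per-chromosome rate statistics. Includes a codon-model
    simulator that generates complete synthetic studies (reference annotation,
    evolved orthologs, a diploid focal individual, transcript fragments and
    error-bearing reads) with truth tables for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    seqinr
Config/testthat/edition: 3
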