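Package: regconverge
Title: Promoter Motif Scanning and Cross-Species Regulatory Convergence
Version: 0.1.0
Authors@R:
    person("Regconverge", "Developers", email = "regconverge@posteo.net",
           role = c("aut", "cre"))
Description: Tools for studying regulatory evolution of pigmentation gene
    networks in birds. Extracts strand-aware promoter windows (2 kb upstream
    to 1 kb downstream of the transcription start site) from genome
    assemblies, scans them with position weight matrices using log-odds
    scores and exact background p-values, counts FDR-passing motif hits into
    transcription-factor by gene binding-strength matrices, and compares
    those matrices across species by Pearson correlation on a phylogeny to
    detect convergent regulatory evolution. Companion expression-side tools
    cover TPM and upper-quartile normalization, differential-expression
    threshold filtering, Ward.D2 clustering, sex-chromosome enrichment and
    dosage classification, and Pfaffl qPCR quantification. A synthetic-data
    module generates genomes, annotations, counts, and species sets with
    planted ground truth so every stage is verifiable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    limma,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    methods
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
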