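Package: trimevol
Title: Evolutionary Analysis of Fish TRIM Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of fish tripartite-motif (TRIM)
    gene families: classification of TRIM proteins into structural classes from
    domain-annotation tables, site-wise Shannon-entropy profiling of protein
    alignments with hypervariable-site calls, maximum-likelihood codon site
    models (M0, M1a, M2a, M7, M8) under a GY94xHKY85 substitution process with
    likelihood-ratio tests and empirical-Bayes identification of positively
    selected sites, greedy recombination-breakpoint detection by corrected AIC
    with per-segment selection re-testing, and a chi-square test for the
    enrichment of a gene family inside marker-centred genomic neighbourhoods
    (for example MHC neighbourhoods). A synthetic-data generator produces codon
    alignments evolved under mixture-omega regimes, recombinant alignments with
    known breakpoints, domain tables and annotated genomes, so that every stage
    of the pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix,
    withr
Config/testthat/edition: 3
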