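Package: compartscan
Title: Compartment-Contrast Analysis of Read-Tracked Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of tissue-compartment cDNA
    libraries assembled with per-library read tracking, as used for the
    digestive tract of the triatomine bug Rhodnius prolixus. Provides the
    contig-by-library read ledger with length filtering and assembly
    summaries; pairwise library contrasts by Pearson chi-square tests with
    an expected-value gate and library-size-normalized fold ratios;
    keyword-vocabulary functional classification of BLAST hit descriptions
    and organism-origin assignment; coding-sequence extraction by homology
    or longest open reading frame with signal-peptide evidence; peritrophin
    chitin-binding-domain motif scanning and mucin-type Ser/Thr-richness
    scoring; proteomic confirmation of deduced proteins from identified
    peptides; and seeded generators of synthetic inputs with the same
    statistical structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
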