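#!/usr/bin/env Rscript
# Proteomic confirmation of the simulated deduced proteins: peptide-to-
# protein matching, the two-ion rule, non-redundant residue coverage and
# best gel fraction.

suppressPackageStartupMessages({
  library(compartscan)
  library(Biostrings)
})

prots <- readAAStringSet("results/sim/proteins.fasta")
proteome <- stats::setNames(as.character(prots), names(prots))
peptides <- utils::read.delim("results/sim/peptides.tsv")

ev <- match_peptides(proteome, peptides)
cf <- confirm(ev, min_ions = 2)
utils::write.table(cf, "results/protein_confirmations.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("Matched ", nrow(ev), " peptide occurrences onto ",
        length(unique(ev$protein_id)), " proteins.")
message(sum(cf$confirmed), " of ", length(proteome),
        " proteins confirmed by >=2 ions; median coverage ",
        stats::median(cf$coverage_residues[cf$confirmed]), " residues.")
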