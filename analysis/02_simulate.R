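#!/usr/bin/env Rscript
# Synthetic study: a read-tracked ledger over the four compartment libraries
# at the reference sequencing depths, with 5% of contigs spiked 10-fold in
# the digestive libraries, plus a proteome with planted chitin-binding
# domains, signal peptides, hit descriptions and peptide identifications.

suppressPackageStartupMessages(library(compartscan))
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
seed <- 42

tot <- reference_library_totals()[c("WB", "AM", "PM", "RE")]
sim <- simulate_catalog(2000, tot, spike_libs = c("AM", "PM", "RE"),
                        spike_fraction = 0.05, fold = 10, seed = seed)
write_counts(sim$catalog, "results/sim/counts.tsv", "results/sim/totals.tsv")
utils::write.table(sim$truth$spiked, "results/sim/spiked_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("Ledger: ", length(sim$catalog$contig_id), " contigs, ",
        nrow(sim$truth$spiked), " spiked 10-fold in AM+PM+RE.")

vocab <- read_vocab()
hits <- simulate_hits(sim$catalog$contig_id, vocab, noise_rate = 0.2,
                      seed = seed, drop_rate = 0.15)
utils::write.table(hits$hits, "results/sim/hits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(contig_id = names(hits$category_of),
                              category = unname(hits$category_of)),
                   "results/sim/category_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("Hits: ", nrow(hits$hits), " descriptions over ",
        length(unique(hits$hits$query_id)), " contigs (15% hitless).")

prot <- simulate_proteome(150, motif_rate = 0.2, signal_rate = 0.4,
                          seed = seed)
writeLines(paste0(">", names(prot$proteins), "\n", prot$proteins),
           "results/sim/proteins.fasta")
writeLines(paste0(">", names(prot$contigs), "\n", prot$contigs),
           "results/sim/contigs.fasta")
utils::write.table(data.frame(protein_id = names(prot$signal),
                              signal = as.integer(prot$signal)),
                   "results/sim/sigp.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(prot$truth$planted_motifs, "results/sim/motif_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("Proteome: 150 proteins, ",
        nrow(prot$truth$planted_motifs), " planted CBDs, ",
        sum(prot$signal), " signal-positive.")

pep <- simulate_peptides(prot$proteins, ions_per_protein = 2, seed = seed)
utils::write.table(pep$peptides, "results/sim/peptides.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("Peptides: ", nrow(pep$peptides), " tryptic-like identifications.")
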