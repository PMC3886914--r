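#!/usr/bin/env Rscript
# CDS extraction from the simulated contigs (longest ORF gated on the
# signal-peptide call), chitin-binding-domain scanning and mucin scoring of
# the deduced proteins.

suppressPackageStartupMessages({
  library(compartscan)
  library(Biostrings)
})

contigs <- readDNAStringSet("results/sim/contigs.fasta")
sigp <- utils::read.delim("results/sim/sigp.tsv")
calls <- stats::setNames(sigp$signal == 1, paste0(sigp$protein_id, "_ctg"))

cds <- do.call(rbind, lapply(names(contigs), function(cid)
  call_cds(cid, as.character(contigs[[cid]]), hits = NULL,
           signal_calls = calls, min_aa = 50)))
utils::write.table(cds, "results/cds.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
writeLines(paste0(">", cds$contig_id, "\n", cds$protein),
           "results/cds_proteins.fasta")
message("Deduced ", nrow(cds), " CDS of ", length(contigs),
        " contigs (signal-peptide gate); ", sum(cds$complete), " complete.")

truth <- utils::read.delim("results/sim/motif_truth.tsv")
scans <- do.call(rbind, lapply(seq_len(nrow(cds)), function(i)
  scan_cbd(cds$protein[i], protein_id = cds$contig_id[i])))
utils::write.table(scans, "results/cbd_domains.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
planted_in_called <- sum(paste0(truth$protein_id, "_ctg") %in% cds$contig_id)
message("CBD scan: ", nrow(scans), " domain instances; ",
        planted_in_called, " planted motifs fall in deduced CDS.")

muc <- do.call(rbind, lapply(seq_len(nrow(cds)), function(i)
  mucin_score(cds$protein[i], protein_id = cds$contig_id[i])))
utils::write.table(muc, "results/mucin_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("Mucin scoring: ", sum(muc$is_mucin_like), " Ser/Thr-rich proteins; ",
        "max window count ", max(muc$candidate_sites), ".")
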