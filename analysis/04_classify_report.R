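#!/usr/bin/env Rscript
# Keyword classification of the simulated hit table and published-style
# class summaries of the contigs each contrast flags at the 10-fold level.

suppressPackageStartupMessages(library(compartscan))

vocab <- read_vocab()
hits <- utils::read.delim("results/sim/hits.tsv", quote = "")
totals <- utils::read.delim("results/sim/totals.tsv")
cat <- load_counts("results/sim/counts.tsv",
                   library_totals = stats::setNames(totals$total_reads,
                                                    totals$library_id))

asg <- classify_contigs(cat$contig_id, hits, vocab)
utils::write.table(asg, "results/classes.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
truth <- utils::read.delim("results/sim/category_truth.tsv")
acc <- mean(asg$category == truth$category[match(asg$contig_id,
                                                 truth$contig_id)])
message(sprintf("Classified %d contigs; %.1f%% agree with the planted truth.",
                nrow(asg), 100 * acc))
message("Category spread: ", length(unique(asg$category)), " categories, ",
        sum(asg$category == "Unknown"), " Unknown.")

for (nm in c("gut_vs_wb", "am_vs_pm", "re_vs_mid")) {
  rows <- utils::read.delim(file.path("results", paste0("de_", nm, ".tsv")))
  tab <- class_summary(asg, rows, scope = "over_table")
  utils::write.table(tab, file.path("results", paste0("classes_", nm, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%-10s %3d flagged contigs across %d categories (top: %s, %.1f%% of reads)",
                  nm, tab$n_contigs[tab$category == "Total"],
                  nrow(tab) - 1L, tab$category[1], tab$pct_reads[1]))
}
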