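vocab <- read_vocab()

test_that("keyword classification weighs position and database rank", {
  hits <- data.frame(query_id = "c1", db = "NR", subject_id = "s1",
                     bitscore = 200, evalue = 1e-40,
                     identity_frac = NA, coverage_frac = NA,
                     description = "cathepsin L-like cysteine proteinase")
  cl <- classify("c1", hits, vocab)
  expect_equal(cl$category, "Digestive enzymes")
  # cathepsin at token 0, proteinase at token 4, NR is rank 4 (factor 1/5)
  expect_equal(cl$score, (1 / 1 + 1 / 5) / 5, tolerance = 1e-12)

  expect_equal(classify("c2", NULL, vocab)$category, "Unknown")
  nov <- data.frame(query_id = "c3", db = "CDD", subject_id = "s",
                    bitscore = 90, evalue = 1e-9, identity_frac = NA,
                    coverage_frac = NA,
                    description = "uncharacterized conserved DUF1234")
  expect_equal(classify("c3", nov, vocab)$category, "Unknown, conserved")
})

test_that("classification is hit-order invariant and never loses to added hits", {
  h1 <- data.frame(query_id = "c", db = c("NR", "KOG"), subject_id = c("a", "b"),
                   bitscore = c(100, 80), evalue = c(1e-20, 1e-30),
                   identity_frac = NA, coverage_frac = NA,
                   description = c("trypsin precursor", "serine protease"))
  expect_equal(classify("c", h1, vocab)$category,
               classify("c", h1[2:1, ], vocab)$category)
  expect_false(classify("c", h1, vocab)$category == "Unknown")
  # earlier token position outranks a later decoy in the same description
  h2 <- data.frame(query_id = "c", db = "NR", subject_id = "a",
                   bitscore = 10, evalue = 1e-5, identity_frac = NA,
                   coverage_frac = NA,
                   description = "lysozyme precursor similar to transporter")
  expect_equal(classify("c", h2, vocab)$category, "Immunity")
})

test_that("origin assignment applies the ratio and e-value gates strictly", {
  expect_equal(assign_origin(list(bacteria = c(520, 1e-60),
                                  invertebrate = c(210, 1e-20))), "bacteria")
  expect_equal(assign_origin(list(vertebrate = c(300, 1e-40),
                                  invertebrate = c(250, 1e-30))), "ambiguous")
  expect_equal(assign_origin(list(virus = c(400, 1e-10),
                                  invertebrate = c(100, 1e-5))), "ambiguous")
  expect_equal(assign_origin(list(invertebrate = c(50, 1e-4))), "invertebrate")
  expect_error(assign_origin(list(bacteria = c(0, 1e-60),
                                  virus = c(0, 1))), "positive")
})

test_that("class summary aggregates flagged contigs and balances", {
  rows <- data.frame(contig_id = paste0("c", 1:6),
                     a = c(100, 50, 30, 7, 260, 3),
                     T_a = 1000, b = 1, T_b = 1000,
                     chi2 = 10, p = 1e-3, min_expected = 10, testable = TRUE,
                     significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                     over_interest = TRUE,
                     over_table = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  asg <- data.frame(contig_id = paste0("c", 1:6),
                    category = c("A", "A", "B", "B", "C", "C"))
  out <- class_summary(asg, rows, scope = "over_table")
  tot <- out[out$category == "Total", ]
  expect_equal(tot$n_reads, 447)
  expect_equal(out$n_reads[out$category == "A"], 150)
  expect_equal(out$reads_per_contig[out$category == "A"], 75)
  expect_equal(out$pct_reads[out$category == "B"],
               round_half_up(100 * 37 / 447, 1))
  body <- out[out$category != "Total", ]
  expect_equal(sum(body$n_reads), tot$n_reads)
  expect_lt(abs(sum(body$pct_reads) - 100), 0.2)
  # a flagged contig without a classification is a hard error naming it
  expect_error(class_summary(asg[-1, ], rows), "c1")
})

test_that("published class tables reproduce from their printed counts", {
  p <- system.file("extdata", "rhodnius_class_tables.tsv",
                   package = "compartscan")
  tabs <- utils::read.delim(p, stringsAsFactors = FALSE)
  for (t in unique(tabs$table)) {
    sub <- tabs[tabs$table == t, ]
    got <- class_table_stats(sub$n_contigs, sub$n_reads, sum(sub$n_reads))
    expect_equal(got$reads_per_contig, sub$reads_per_contig)
    expect_equal(got$pct_reads, sub$pct_reads)
  }
})
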