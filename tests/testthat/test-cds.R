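test_that("ORF finding translates ATG..stop in all six frames", {
  expect_equal(nrow(find_orfs("AAATTTCCC", min_aa = 2)), 0L)
  fw <- find_orfs("GGATGAAATAGGG", min_aa = 2)
  expect_equal(nrow(fw), 1L)
  expect_equal(fw$protein, "MK")
  expect_equal(c(fw$start, fw$end), c(2L, 11L))
  expect_equal(fw$strand, "+")
  rv <- find_orfs("CCCTATTTCATCC", min_aa = 2)
  expect_equal(rv$protein, "MK")
  expect_equal(rv$strand, "-")
  expect_equal(c(rv$start, rv$end), c(2L, 11L))
  # N-containing codons translate as X and never start or stop
  nx <- find_orfs("GGATGANATAGGG", min_aa = 2)
  expect_equal(nx$protein, "MX")
  expect_error(find_orfs("ATGRAT"), "outside")
})

test_that("ORF calls are strand-symmetric and retranslate from coordinates", {
  set.seed(13)
  nt <- c("A", "C", "G", "T")
  for (i in 1:20) {
    s <- paste(sample(nt, 300, replace = TRUE), collapse = "")
    a <- find_orfs(s, min_aa = 10)
    b <- find_orfs(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s))), min_aa = 10)
    expect_equal(sort(a$protein), sort(b$protein))
    # mirrored coordinates swap strands
    b_m <- data.frame(start = 300L - b$end, end = 300L - b$start,
                      strand = ifelse(b$strand == "+", "-", "+"))
    key <- function(d) sort(paste(d$start, d$end, d$strand))
    expect_equal(key(a), key(b_m))
    # retranslation oracle via Biostrings on the reported span
    for (j in seq_len(nrow(a))) {
      span <- substr(s, a$start[j] + 1L, a$end[j])
      if (a$strand[j] == "-")
        span <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(span)))
      prot <- as.character(Biostrings::translate(Biostrings::DNAString(span)))
      expect_equal(sub("\\*$", "", prot), a$protein[j])
    }
  }
})

test_that("CDS calling gates the ORF route on a signal-peptide call", {
  sim <- simulate_proteome(6, motif_rate = 0, signal_rate = 1, seed = 31)
  cid <- names(sim$contigs)[1]
  pid <- sub("_ctg$", "", cid)
  calls <- stats::setNames(TRUE, cid)
  got <- call_cds(cid, sim$contigs[[cid]], hits = NULL, signal_calls = calls,
                  min_aa = 50)
  expect_equal(got$route, "orf_signal")
  expect_equal(got$protein, unname(sim$proteins[pid]))
  tr <- sim$truth$cds[sim$truth$cds$contig_id == cid, ]
  expect_equal(c(got$start, got$end, got$strand),
               c(tr$start, tr$end, tr$strand))
  # same contig without a positive call yields nothing
  expect_null(call_cds(cid, sim$contigs[[cid]], hits = NULL,
                       signal_calls = stats::setNames(FALSE, cid)))
})

test_that("similarity-guided CDS extends a planted homology window in frame", {
  # upstream extension: region over the 3rd/4th codons walks back to the ATG
  s <- paste0("TAA", "ATGAAACCCGGGTAA")
  hit <- data.frame(query_id = "h", db = "NR", subject_id = "s",
                    bitscore = 100, evalue = 1e-30, identity_frac = NA,
                    coverage_frac = NA, description = "x",
                    q_start = 9L, q_end = 15L)
  ext <- call_cds("h", s, hits = hit, signal_calls = logical(), min_aa = 1)
  expect_equal(c(ext$start, ext$end), c(3L, 18L))
  expect_equal(ext$protein, "MKPG")
  expect_true(ext$complete)

  sim <- simulate_proteome(4, motif_rate = 0, signal_rate = 0, seed = 77)
  tr <- sim$truth$cds
  for (k in seq_len(nrow(tr))) {
    cid <- tr$contig_id[k]
    # aligned region anchored at the true start codon, in the CDS frame
    if (tr$strand[k] == "+") {
      qs <- tr$start[k]; qe <- tr$end[k] - 3L
    } else {
      qs <- tr$end[k]; qe <- tr$start[k] + 3L  # swapped order = minus strand
    }
    hits <- data.frame(query_id = cid, db = "NR", subject_id = "s",
                       bitscore = 300, evalue = 1e-50, identity_frac = NA,
                       coverage_frac = NA, description = "x",
                       q_start = qs, q_end = qe)
    got <- call_cds(cid, sim$contigs[[cid]], hits = hits,
                    signal_calls = logical(), min_aa = 50)
    expect_equal(got$route, "similarity")
    expect_equal(got$strand, tr$strand[k])
    expect_equal(c(got$start, got$end), c(tr$start[k], tr$end[k]))
    expect_true(got$complete)
    expect_equal(got$protein,
                 unname(sim$proteins[sub("_ctg$", "", cid)]))
  }
})

test_that("coverage filter is strict at the 90 percent boundary", {
  expect_true(coverage_filter(list(coverage_frac = 0.95)))
  expect_false(coverage_filter(list(coverage_frac = 0.90)))
  expect_error(coverage_filter(list(coverage_frac = NA)), "coverage")
  set.seed(4)
  cov <- round(runif(20, 0.5, 1), 3)
  got <- vapply(cov, function(cv) coverage_filter(list(coverage_frac = cv)),
                logical(1))
  expect_equal(got, cov > 0.90)
})
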