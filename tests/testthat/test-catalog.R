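test_that("load_counts parses a ledger and enforces its invariants", {
  p <- write_counts_tsv(data.frame(contig_id = c("c1", "c2", "c3"),
                                   length = c(300L, 251L, 250L),
                                   WB = c(10L, 0L, 3L), AM = c(1L, 2L, 0L)))
  cat <- load_counts(p, library_totals = c(WB = 1000, AM = 500))
  expect_length(cat$contig_id, 3L)
  expect_equal(cat$libraries$library_id, c("WB", "AM"))
  expect_equal(unname(cat$counts["c2", ]), c(0L, 2L))

  # undeclared column named in the error
  expect_error(load_counts(p, library_totals = c(WB = 1000)), "AM")
  # column sum above the declared total
  expect_error(load_counts(p, library_totals = c(WB = 12, AM = 500)), "WB")
  # duplicates and negatives rejected
  pd <- write_counts_tsv(data.frame(contig_id = c("c1", "c1"),
                                    length = c(300L, 400L), WB = c(1L, 1L)))
  expect_error(load_counts(pd, library_totals = c(WB = 10)), "duplicate")
  pn <- write_counts_tsv(data.frame(contig_id = "c1", length = 300L, WB = -1L))
  expect_error(load_counts(pn, library_totals = c(WB = 10)), "negative")
})

test_that("a written catalog reloads with identical counts and lengths", {
  set.seed(7)
  sim <- simulate_catalog(40, c(L1 = 5000, L2 = 3000), seed = 7)
  p <- tempfile(fileext = ".tsv")
  write_counts(sim$catalog, p)
  back <- load_counts(p, library_totals = c(L1 = 5000, L2 = 3000))
  expect_identical(back$counts, sim$catalog$counts)
  expect_identical(back$length_nt, sim$catalog$length_nt)
  expect_identical(back$contig_id, sim$catalog$contig_id)
})

test_that("length filtering is strict, idempotent and monotone", {
  cat <- catalog(data.frame(library_id = "L", total_reads = 100),
                 data.frame(contig_id = paste0("c", 1:3),
                            length_nt = c(250L, 251L, 400L), L = c(1L, 2L, 3L)))
  expect_equal(length(filter_by_length(cat, 250)$contig_id), 2L)
  expect_equal(filter_by_length(cat, 0)$contig_id, cat$contig_id)

  set.seed(11)
  lens <- sample(100:10000, 100, replace = TRUE)
  big <- catalog(data.frame(library_id = "L", total_reads = 1000),
                 data.frame(contig_id = paste0("c", 1:100), length_nt = lens,
                            L = rep(1L, 100)))
  f <- filter_by_length(big, 999)
  expect_equal(length(f$contig_id), sum(lens > 999))
  expect_identical(filter_by_length(f, 999)$contig_id, f$contig_id)
  thresholds <- c(0, 250, 999, 1999, 5000)
  kept <- vapply(thresholds,
                 function(t) length(filter_by_length(big, t)$contig_id),
                 integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("assembly summary matches brute-force enumeration and is order-invariant", {
  set.seed(3)
  lens <- sample(150:3000, 50, replace = TRUE)
  reads <- sample(0:50, 50, replace = TRUE)
  mk <- function(ord) catalog(
    data.frame(library_id = "L", total_reads = 5000),
    data.frame(contig_id = paste0("c", seq_along(lens))[ord],
               length_nt = lens[ord], L = reads[ord]))
  s1 <- assembly_summary(mk(1:50), thresholds = c(250, 499, 999, 1999))
  expect_equal(s1$by_threshold$n_contigs_above,
               vapply(c(250, 499, 999, 1999),
                      function(t) sum(lens > t), integer(1)))
  expect_equal(s1$total_reads, sum(reads))
  s2 <- assembly_summary(mk(sample(50)), thresholds = c(250, 499, 999, 1999))
  expect_equal(s2$by_threshold, s1$by_threshold)
  expect_equal(s2$total_reads, s1$total_reads)

  empty <- catalog(data.frame(library_id = "L", total_reads = 10),
                   data.frame(contig_id = character(), length_nt = integer(),
                              L = integer()))
  se <- assembly_summary(empty, thresholds = 250)
  expect_equal(se$by_threshold$n_contigs_above, 0L)
  expect_equal(se$total_reads, 0)
})

test_that("whole-body pooling design enumerates the life-cycle preparations", {
  sch <- wb_pooling_scheme()
  expect_equal(nrow(sch), 45L)
  expect_equal(sum(sch$stage == "instar5"), 9L)
  expect_equal(sum(sch$stage == "egg"), 4L)
})
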