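test_that("gated 2x2 chi-square agrees with the reference implementation", {
  # equal proportions: statistic 0, p 1
  eq <- chi2_2x2(10, 1000, 10, 1000)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  expect_equal(eq$min_expected, 10)
  expect_true(eq$testable)

  # frozen from the Pearson cross-product formula and chisq.test(correct=FALSE)
  ct <- chi2_2x2(30, 1000, 10, 1000)
  expect_equal(ct$chi2, 10.20408, tolerance = 1e-6)
  expect_equal(ct$p, 0.00140130, tolerance = 1e-5)
  expect_equal(ct$min_expected, 20)
  ref <- stats::chisq.test(matrix(c(30, 10, 970, 990), 2, byrow = TRUE),
                           correct = FALSE)
  expect_equal(ct$chi2, unname(ref$statistic))
  expect_equal(ct$p, unname(ref$p.value))

  # below the expected-value gate: undefined, never significant
  gate <- chi2_2x2(4, 1000, 0, 1000)
  expect_equal(gate$min_expected, 2)
  expect_false(gate$testable)
  expect_true(is.na(gate$chi2) && is.na(gate$p))

  expect_error(chi2_2x2(1001, 1000, 0, 1000), "exceeds")
})

test_that("chi-square is symmetric and matches chisq.test over random tables", {
  set.seed(21)
  for (i in 1:40) {
    T_a <- sample(500:5000, 1); T_b <- sample(500:5000, 1)
    a <- rbinom(1, T_a, 0.02); b <- rbinom(1, T_b, 0.02)
    x <- chi2_2x2(a, T_a, b, T_b)
    y <- chi2_2x2(b, T_b, a, T_a)
    expect_equal(x$chi2, y$chi2)
    expect_equal(x$p, y$p)
    expect_equal(x$min_expected, y$min_expected)
    expect_identical(x$testable, y$testable)
    if (x$testable && a + b > 0) {
      ref <- stats::chisq.test(matrix(c(a, b, T_a - a, T_b - b), 2,
                                      byrow = TRUE), correct = FALSE)
      expect_equal(x$chi2, unname(ref$statistic), tolerance = 1e-10)
    }
  }
})

test_that("normalized fold ratio follows the pseudocount formula", {
  expect_equal(normalized_fold(0, 1000, 5, 1000), 0)
  expect_equal(normalized_fold(100, 1000, 49, 500), 1.0)
  # strictly increasing in a, strictly decreasing in b
  set.seed(5)
  a <- sample(0:200, 30); b <- sample(0:200, 30)
  f0 <- normalized_fold(a, 1000, b, 2000)
  expect_true(all(normalized_fold(a + 1, 1000, b, 2000) > f0))
  expect_true(all(normalized_fold(a, 1000, b + 1, 2000) < f0))
  expect_true(all(f0 >= 0))
  expect_identical(f0 == 0, a == 0)
})

test_that("run_contrast flags the enriched contig of the toy catalog", {
  rows <- run_contrast(toy_catalog(), contrast_spec("AM", "PM"))
  x <- rows[rows$contig_id == "X", ]; y <- rows[rows$contig_id == "Y", ]
  expect_true(x$testable && x$significant && x$over_interest)
  expect_false(x$over_table)   # fold 40/5 = 8 < 10
  expect_equal(x$fold, 8)
  expect_false(y$significant || y$over_interest)
  # all-zero contig: fold 0 and below the gate
  cat0 <- catalog(data.frame(library_id = c("AM", "PM"),
                             total_reads = c(1000, 1000)),
                  data.frame(contig_id = "Z", length_nt = 100L,
                             AM = 0L, PM = 0L))
  z <- run_contrast(cat0, contrast_spec("AM", "PM"))
  expect_equal(z$fold, 0)
  expect_false(z$testable)
  expect_error(run_contrast(toy_catalog(), contrast_spec("AM", "RE")), "RE")
})

test_that("multi-library sides pool counts and totals by summation", {
  cat <- catalog(data.frame(library_id = c("AM", "PM", "WB"),
                            total_reads = c(1000, 2000, 8000)),
                 data.frame(contig_id = "c", length_nt = 300L,
                            AM = 30L, PM = 50L, WB = 20L))
  r <- run_contrast(cat, contrast_spec(c("AM", "PM"), "WB"))
  expect_equal(r$a, 80); expect_equal(r$T_a, 3000)
  expect_equal(r$b, 20); expect_equal(r$T_b, 8000)
  expect_equal(r$fold, (80 * 8000 / 3000) / 21)
})

test_that("null simulation is calibrated and the gate is never violated", {
  sim <- simulate_catalog(2000, c(L1 = 1e5, L2 = 1e5), seed = 42)
  rows <- run_contrast(sim$catalog, contrast_spec("L1", "L2"))
  frac <- mean(rows$p[rows$testable] < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
  expect_false(any(rows$significant & rows$min_expected <= 5))
  # flat renormalization of a null spike changes nothing
  expect_false(any(rows$over_interest & !rows$significant))
})

test_that("well-expressed 10-fold spikes are recovered as significant 2-fold hits", {
  sens <- vapply(1:3, function(s) {
    sim <- simulate_catalog(2000, c(L1 = 1e5, L2 = 1e5), spike_libs = "L1",
                            spike_fraction = 0.05, fold = 10, seed = s)
    rows <- run_contrast(sim$catalog, contrast_spec("L1", "L2"))
    idx <- match(sim$truth$spiked$contig_id, rows$contig_id)
    strong <- sim$truth$spiked$baseline_p * 10 * 1e5 >= 50
    mean(rows$over_interest[idx][strong])
  }, numeric(1))
  expect_true(all(sens >= 0.95))
})

test_that("Benjamini-Hochberg flag tightens the significance call", {
  sim <- simulate_catalog(500, c(L1 = 5e4, L2 = 5e4), seed = 9)
  raw <- run_contrast(sim$catalog, contrast_spec("L1", "L2"))
  bh <- run_contrast(sim$catalog, contrast_spec("L1", "L2", p_adjust = "BH"))
  expect_true(sum(bh$significant) <= sum(raw$significant))
  expect_equal(bh$p, raw$p)  # raw p column is unchanged
})
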