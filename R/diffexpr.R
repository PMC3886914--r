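#' Specification of a library-set contrast
#'
#' A contrast compares, per contig, the reads drawn from a numerator library
#' set against those from a disjoint denominator set. Significance is a
#' Pearson chi-square test on the 2x2 table of (reads hitting the contig,
#' remaining reads) per side, applied only when the smallest expected cell
#' value exceeds `min_expected` — the gate that keeps the asymptotic test
#' honest for low-count contigs. Effect size is the normalized fold ratio of
#' [normalized_fold()].
#'
#' @param numerator,denominator character vectors of library ids; disjoint,
#'   non-empty. Multi-library sides are pooled by summation.
#' @param alpha significance level (default 0.05).
#' @param min_expected expected-value gate; a contig is testable only when the
#'   minimum expected cell count is strictly greater than this (default 5).
#' @param interest_fold fold change considered of interest when significant
#'   (default 2).
#' @param table_fold stringent fold used for summary tables (default 10); must
#'   be at least `interest_fold`.
#' @param correct apply the Yates continuity correction (default FALSE; the
#'   expected-value gate already excludes the tables the correction targets).
#' @param p_adjust multiple-testing correction passed to [stats::p.adjust()];
#'   `"none"` (default) reproduces raw per-contig P values, `"BH"` switches
#'   the significance call to Benjamini-Hochberg adjusted values.
#' @return an object of class `contrast_spec`.
#' @export
contrast_spec <- function(numerator, denominator, alpha = 0.05,
                          min_expected = 5, interest_fold = 2, table_fold = 10,
                          correct = FALSE, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  numerator <- as.character(numerator); denominator <- as.character(denominator)
  if (!length(numerator) || !length(denominator))
    stop("numerator and denominator library sets must be non-empty")
  if (length(intersect(numerator, denominator)))
    stop("numerator and denominator library sets must be disjoint")
  stopifnot(alpha > 0, alpha < 1, min_expected >= 0,
            interest_fold >= 1, table_fold >= interest_fold)
  structure(list(numerator = numerator, denominator = denominator,
                 alpha = alpha, min_expected = min_expected,
                 interest_fold = interest_fold, table_fold = table_fold,
                 correct = correct, p_adjust = p_adjust),
            class = "contrast_spec")
}

#' Gated Pearson chi-square test on a 2x2 read-count table
#'
#' Builds the table `[[a, b], [T_a - a, T_b - b]]` — reads hitting the contig
#' versus the rest of each library set — and evaluates the Pearson chi-square
#' statistic (df = 1) with its upper-tail probability. The test is applied
#' only when the smallest of the four expected cell values under independence
#' strictly exceeds `min_expected`; otherwise `chi2` and `p` are `NA` and the
#' contig must be treated as not significant.
#'
#' All arguments are vectorized over contigs.
#'
#' @param a,b reads hitting the contig in the numerator / denominator set.
#' @param T_a,T_b total reads of the numerator / denominator set.
#' @param min_expected the gate threshold (strict; default 5).
#' @param correct apply the Yates continuity correction.
#' @return data.frame with columns `chi2`, `p`, `min_expected`, `testable`.
#' @export
chi2_2x2 <- function(a, T_a, b, T_b, min_expected = 5, correct = FALSE) {
  # doubles throughout: the cross product overflows 32-bit integers
  a <- as.numeric(a); b <- as.numeric(b)
  T_a <- as.numeric(T_a); T_b <- as.numeric(T_b)
  if (any(T_a <= 0) || any(T_b <= 0)) stop("library totals must be positive")
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  if (any(a > T_a) || any(b > T_b))
    stop("per-contig count exceeds its library-set total")
  N <- T_a + T_b
  r1 <- a + b          # reads hitting the contig
  r2 <- N - r1         # reads elsewhere
  # expected values under independence of (hit contig) x (library set)
  e11 <- r1 * T_a / N; e12 <- r1 * T_b / N
  e21 <- r2 * T_a / N; e22 <- r2 * T_b / N
  min_exp <- pmin(e11, e12, e21, e22)
  testable <- min_exp > min_expected
  # Pearson statistic in cross-product form: N (ad - bc)^2 / (r1 r2 c1 c2)
  d <- abs(a * (T_b - b) - b * (T_a - a))
  if (correct) d <- pmax(0, d - N / 2)
  chi2 <- N * d^2 / (r1 * r2 * T_a * T_b)
  chi2[r1 == 0 | r2 == 0] <- 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  chi2[!testable] <- NA_real_
  p[!testable] <- NA_real_
  data.frame(chi2 = chi2, p = p, min_expected = min_exp, testable = testable)
}

#' Library-size-normalized fold ratio
#'
#' `(a * T_b / T_a) / (b + 1)`: the numerator count is scaled by the ratio of
#' the library-set totals and one read is added to the denominator count so
#' contigs absent from the denominator still get a finite ratio. Values above
#' 1 mean enrichment in the numerator set; the ratio is 0 exactly when `a` is.
#'
#' @inheritParams chi2_2x2
#' @return numeric vector of fold ratios.
#' @export
normalized_fold <- function(a, T_a, b, T_b) {
  a <- as.numeric(a); b <- as.numeric(b)
  T_a <- as.numeric(T_a); T_b <- as.numeric(T_b)
  if (any(T_a <= 0)) stop("numerator library-set total must be positive")
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  (a * T_b / T_a) / (b + 1)
}

#' Run a contrast over a catalog
#'
#' Pools counts and declared totals over each side's libraries, then evaluates
#' the gated chi-square test and normalized fold ratio for every contig.
#'
#' @param cat a [catalog].
#' @param spec a [contrast_spec].
#' @return data.frame, one row per contig in catalog order, with columns
#'   `contig_id`, `a`, `T_a`, `b`, `T_b`, `chi2`, `p`, `min_expected`,
#'   `testable`, `fold`, `significant`, `over_interest`, `over_table`.
#'   `significant = testable & p < alpha` (adjusted p when BH is enabled);
#'   `over_interest = significant & fold >= interest_fold`;
#'   `over_table = significant & fold >= table_fold`.
#' @export
run_contrast <- function(cat, spec) {
  stopifnot(inherits(cat, "catalog"), inherits(spec, "contrast_spec"))
  libs <- cat$libraries$library_id
  unknown <- setdiff(c(spec$numerator, spec$denominator), libs)
  if (length(unknown))
    stop("contrast names library absent from catalog: ",
         paste(unknown, collapse = ", "))
  tot <- stats::setNames(cat$libraries$total_reads, libs)
  a <- rowSums(cat$counts[, spec$numerator, drop = FALSE])
  b <- rowSums(cat$counts[, spec$denominator, drop = FALSE])
  T_a <- sum(tot[spec$numerator]); T_b <- sum(tot[spec$denominator])

  ct <- chi2_2x2(a, T_a, b, T_b, min_expected = spec$min_expected,
                 correct = spec$correct)
  fold <- normalized_fold(a, T_a, b, T_b)
  p_eff <- ct$p
  if (spec$p_adjust == "BH")
    p_eff[ct$testable] <- stats::p.adjust(ct$p[ct$testable], method = "BH")
  significant <- ct$testable & !is.na(p_eff) & p_eff < spec$alpha
  data.frame(contig_id = cat$contig_id,
             a = a, T_a = T_a, b = b, T_b = T_b,
             chi2 = ct$chi2, p = ct$p, min_expected = ct$min_expected,
             testable = ct$testable, fold = fold,
             significant = significant,
             over_interest = significant & fold >= spec$interest_fold,
             over_table = significant & fold >= spec$table_fold,
             row.names = NULL)
}

#' Write a contrast result table
#'
#' Fold ratios are printed to one decimal, the convention used when quoting
#' per-contig enrichment; other numeric columns keep full precision.
#'
#' @param rows result of [run_contrast()].
#' @param path output TSV path.
#' @export
write_contrast <- function(rows, path) {
  out <- rows
  out$fold <- round(out$fold, 1)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
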