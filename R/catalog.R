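#' Contig-by-library read ledger
#'
#' A `catalog` couples the declared per-library sequencing totals with the
#' per-contig, per-library read counts that a read-tracking assembler
#' deconvolutes into each contig. Library totals are declared independently of
#' the count table because reads excluded from the assembly (short contigs,
#' singletons) still count toward the library's sequencing depth and toward the
#' expected values of the chi-square contrasts.
#'
#' @param libraries data.frame with columns `library_id` (unique character
#'   labels, e.g. `"WB"`, `"AM"`) and `total_reads` (non-negative integers).
#' @param contigs data.frame with columns `contig_id` (unique), `length_nt`
#'   (positive integers), and one non-negative integer count column per
#'   declared library. Missing count columns are treated as all-zero.
#' @param sequences optional named character vector (or
#'   [Biostrings::DNAStringSet]) of contig nucleotide sequences over
#'   `A,C,G,T,N`; names must be contig ids and lengths must equal `length_nt`.
#'
#' @return An object of class `catalog`: a list with elements `libraries`
#'   (data.frame), `contig_id`, `length_nt`, `counts` (integer matrix, one row
#'   per contig, one column per library) and `sequences` (named character or
#'   NULL).
#' @export
catalog <- function(libraries, contigs, sequences = NULL) {
  stopifnot(is.data.frame(libraries),
            all(c("library_id", "total_reads") %in% names(libraries)),
            is.data.frame(contigs),
            all(c("contig_id", "length_nt") %in% names(contigs)))
  libraries$library_id <- as.character(libraries$library_id)
  if (anyDuplicated(libraries$library_id))
    stop("duplicate library_id in library specification")
  if (any(libraries$total_reads < 0))
    stop("library total_reads must be non-negative")

  ids <- as.character(contigs$contig_id)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate contig_id: ", paste(dup, collapse = ", "))
  }
  len <- as.integer(contigs$length_nt)
  if (any(is.na(len)) || any(len <= 0))
    stop("contig length_nt must be positive integers")

  lib_ids <- libraries$library_id
  extra <- setdiff(setdiff(names(contigs), c("contig_id", "length_nt")), lib_ids)
  if (length(extra))
    stop("count column(s) for undeclared library: ", paste(extra, collapse = ", "))

  counts <- matrix(0L, nrow = length(ids), ncol = length(lib_ids),
                   dimnames = list(ids, lib_ids))
  for (lib in lib_ids) {
    if (lib %in% names(contigs)) {
      v <- contigs[[lib]]
      v[is.na(v)] <- 0L
      if (any(v < 0)) stop("negative read count in library ", lib)
      counts[, lib] <- as.integer(v)
    }
  }
  csums <- colSums(counts)
  tot <- stats::setNames(as.numeric(libraries$total_reads), lib_ids)
  over <- lib_ids[csums > tot[lib_ids]]
  if (length(over))
    stop("column sum exceeds declared library total for: ",
         paste(over, collapse = ", "))

  if (!is.null(sequences)) {
    sequences <- as.character(sequences)
    if (is.null(names(sequences)) || !all(names(sequences) %in% ids))
      stop("sequence names must be contig ids present in the catalog")
    bad <- names(sequences)[nchar(sequences) != len[match(names(sequences), ids)]]
    if (length(bad))
      stop("sequence length disagrees with length_nt for: ",
           paste(bad, collapse = ", "))
    if (any(grepl("[^ACGTN]", toupper(sequences))))
      stop("contig sequences must be over {A,C,G,T,N}")
    sequences <- toupper(sequences)
  }

  structure(list(libraries = libraries[, c("library_id", "total_reads")],
                 contig_id = ids, length_nt = len, counts = counts,
                 sequences = sequences),
            class = "catalog")
}

#' @export
print.catalog <- function(x, ...) {
  cat(sprintf("catalog: %d contigs x %d libraries (%s)\n",
              length(x$contig_id), nrow(x$libraries),
              paste(x$libraries$library_id, collapse = ", ")))
  cat(sprintf("  reads in catalog: %s of %s declared (%.0f%%)\n",
              format(sum(x$counts), big.mark = ","),
              format(sum(x$libraries$total_reads), big.mark = ","),
              100 * sum(x$counts) / max(1, sum(x$libraries$total_reads))))
  invisible(x)
}

#' Read a contig-by-library count table
#'
#' The table is tab-separated with header `contig_id`, `length`, then one
#' column per library. Empty cells count as zero.
#'
#' @param path path to the counts TSV.
#' @param library_totals named numeric vector of declared per-library read
#'   totals covering every count column, or NULL with `infer_totals = TRUE`.
#' @param infer_totals if TRUE, totals are taken as the column sums of the
#'   table (appropriate only when every sequenced read reached the assembly).
#' @param fasta optional path to a FASTA file of contig sequences whose ids
#'   match `contig_id`.
#' @return a [catalog].
#' @export
load_counts <- function(path, library_totals = NULL, infer_totals = FALSE,
                        fasta = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("contig_id", "length") %in% names(df)))
    stop("counts table must have 'contig_id' and 'length' columns")
  lib_cols <- setdiff(names(df), c("contig_id", "length"))
  if (infer_totals) {
    library_totals <- vapply(lib_cols,
                             function(l) sum(df[[l]], na.rm = TRUE), numeric(1))
  }
  if (is.null(library_totals))
    stop("library_totals must be supplied (or infer_totals = TRUE)")
  missing <- setdiff(lib_cols, names(library_totals))
  if (length(missing))
    stop("no declared total for library column: ", paste(missing, collapse = ", "))
  names(df)[names(df) == "length"] <- "length_nt"
  seqs <- NULL
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seqs <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  catalog(libraries = data.frame(library_id = lib_cols,
                                 total_reads = as.numeric(library_totals[lib_cols])),
          contigs = df, sequences = seqs)
}

#' Write a catalog's count table
#'
#' Inverse of [load_counts()]: writes `contig_id`, `length`, then one column
#' per library, tab-separated. Totals are written alongside when `totals_path`
#' is given (two columns: `library_id`, `total_reads`).
#'
#' @param cat a [catalog].
#' @param path output TSV path.
#' @param totals_path optional path for the totals TSV.
#' @export
write_counts <- function(cat, path, totals_path = NULL) {
  df <- data.frame(contig_id = cat$contig_id, length = cat$length_nt,
                   cat$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(totals_path))
    utils::write.table(cat$libraries, totals_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Filter contigs by length
#'
#' Retains contigs strictly longer than `min_exclusive` nucleotides ("above
#' 250 nt" means 251 and longer). Library declarations are unchanged, so
#' downstream contrasts keep using the full sequencing totals.
#'
#' @param cat a [catalog].
#' @param min_exclusive non-negative integer; contigs with
#'   `length_nt > min_exclusive` are kept.
#' @return a [catalog] with the retained contigs, in input order.
#' @export
filter_by_length <- function(cat, min_exclusive) {
  stopifnot(inherits(cat, "catalog"), min_exclusive >= 0)
  keep <- cat$length_nt > min_exclusive
  seqs <- cat$sequences
  if (!is.null(seqs)) seqs <- seqs[names(seqs) %in% cat$contig_id[keep]]
  structure(list(libraries = cat$libraries,
                 contig_id = cat$contig_id[keep],
                 length_nt = cat$length_nt[keep],
                 counts = cat$counts[keep, , drop = FALSE],
                 sequences = seqs),
            class = "catalog")
}

#' Assembly summary statistics
#'
#' Counts contigs strictly longer than each threshold and reports how many of
#' the declared sequencing reads the catalog accounts for.
#'
#' @param cat a [catalog].
#' @param thresholds ascending integer length thresholds (nt).
#' @return list with `by_threshold` (data.frame: `threshold`,
#'   `n_contigs_above`), `total_reads` (reads in the catalog), `grand_total`
#'   (sum of declared library totals) and `pct_of_total` (integer percent of
#'   the grand total held by the catalog).
#' @export
assembly_summary <- function(cat, thresholds = c(250L, 499L, 999L, 1999L)) {
  stopifnot(inherits(cat, "catalog"), !is.unsorted(thresholds))
  n_above <- vapply(thresholds,
                    function(t) sum(cat$length_nt > t), integer(1))
  total_reads <- sum(cat$counts)
  grand <- sum(cat$libraries$total_reads)
  list(by_threshold = data.frame(threshold = as.integer(thresholds),
                                 n_contigs_above = n_above),
       total_reads = total_reads,
       grand_total = grand,
       pct_of_total = if (grand > 0) as.integer(round(100 * total_reads / grand)) else 0L)
}

#' Whole-body library pooling design
#'
#' The whole-body (WB) reference library pools RNA preparations across the
#' full life cycle: eggs at four ages, each nymphal instar and the adults at
#' fasting plus a stage-specific series of days after feeding (DAF). This
#' function enumerates that design, one row per pooled RNA preparation.
#'
#' @return data.frame with columns `stage` and `timepoint` (`"day0"`,
#'   `"fasting"` or `"DAF<k>"`), 45 rows in total.
#' @export
wb_pooling_scheme <- function() {
  stages <- list(
    egg            = c("day0", "day2", "day5", "day7"),
    instar1        = c("fasting", paste0("DAF", c(2, 5, 7))),
    instar2        = c("fasting", paste0("DAF", c(2, 5, 7, 9))),
    instar3        = c("fasting", paste0("DAF", c(2, 5, 7, 9))),
    instar4        = c("fasting", paste0("DAF", c(2, 5, 7, 9, 12))),
    instar5        = c("fasting", paste0("DAF", c(2, 5, 7, 9, 12, 14, 17, 19))),
    adult_male     = c("fasting", paste0("DAF", c(2, 5, 7, 9, 12))),
    adult_female   = c("fasting", paste0("DAF", c(2, 5, 7, 9, 12)))
  )
  data.frame(stage = rep(names(stages), lengths(stages)),
             timepoint = unlist(stages, use.names = FALSE))
}

#' Declared library totals of the reference dataset
#'
#' The eight cDNA libraries of the triatomine study with their 454 read
#' totals: whole body (WB), anterior midgut (AM), posterior midgut (PM),
#' rectum (RE), fat body (FB), Malpighian tubule (MT), ovary (OV), testis
#' (TE). Shipped as a plain TSV under `extdata`.
#'
#' @return named numeric vector of read totals, names are library ids.
#' @export
reference_library_totals <- function() {
  path <- system.file("extdata", "rhodnius_library_totals.tsv",
                      package = "compartscan", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$total_reads), df$library_id)
}
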