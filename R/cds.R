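#' @importFrom Biostrings DNAString reverseComplement GENETIC_CODE
NULL

# translate a vector of codon strings with the standard genetic code;
# codons containing N (or any ambiguity) become X and never start/stop
.translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  aa
}

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# maximal ORFs (most upstream ATG per stop-free stretch) in the three forward
# frames of one strand; coordinates 0-based half-open on that strand
.scan_strand <- function(seq, min_aa) {
  n <- nchar(seq)
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < 2L) next
    starts_at <- frame + 3L * (seq_len(ncod) - 1L) + 1L  # 1-based
    codons <- substring(seq, starts_at, starts_at + 2L)
    is_stop <- codons %in% stops
    is_atg <- codons == "ATG"
    open_from <- NA_integer_   # codon index of the ORF's ATG
    for (i in seq_len(ncod)) {
      if (is.na(open_from) && is_atg[i]) open_from <- i
      if (!is.na(open_from) && is_stop[i]) {
        aa_len <- i - open_from          # protein length, stop excluded
        if (aa_len >= min_aa) {
          prot <- paste(.translate_codons(codons[open_from:(i - 1L)]),
                        collapse = "")
          out[[length(out) + 1L]] <- list(
            start = frame + 3L * (open_from - 1L),        # 0-based
            end = frame + 3L * i,                         # past the stop codon
            frame = frame, protein = prot)
        }
        open_from <- NA_integer_
      }
    }
  }
  out
}

#' Find open reading frames in all six frames
#'
#' An ORF runs from an ATG to the first in-frame stop (TAA/TAG/TGA). For each
#' stop-bounded stretch the most upstream ATG is reported (the maximal ORF).
#' Codons containing N translate as X and never act as start or stop.
#' Coordinates are 0-based half-open on the plus strand of the input, stop
#' codon included, with a strand flag; `frame` is the reading frame on the
#' ORF's own strand.
#'
#' @param sequence nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param min_aa minimum protein length in residues (stop excluded).
#' @param contig_id optional id copied into the result.
#' @return data.frame `contig_id`, `start`, `end`, `strand`, `frame`,
#'   `protein`, `complete` (all TRUE here: Met through stop), sorted by
#'   `(start, end)`.
#' @export
find_orfs <- function(sequence, min_aa = 50, contig_id = NA_character_) {
  stopifnot(min_aa >= 1)
  seq <- toupper(sequence)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}")
  n <- nchar(seq)
  plus <- .scan_strand(seq, min_aa)
  minus <- .scan_strand(.revcomp(seq), min_aa)
  rows <- c(
    lapply(plus, function(o)
      data.frame(contig_id = contig_id, start = o$start, end = o$end,
                 strand = "+", frame = o$frame, protein = o$protein,
                 complete = TRUE)),
    lapply(minus, function(o)
      data.frame(contig_id = contig_id, start = n - o$end, end = n - o$start,
                 strand = "-", frame = o$frame, protein = o$protein,
                 complete = TRUE))
  )
  if (!length(rows))
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(), frame = integer(),
                      protein = character(), complete = logical()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

# extend a hit's aligned region to an in-frame CDS: back to the in-frame ATG
# at or upstream of the region (else the region start), forward to the first
# in-frame stop (else the sequence end); strand-local coordinates
.extend_to_cds <- function(seq, region_start, region_end) {
  n <- nchar(seq)
  frame <- region_start %% 3L
  codon_start_1b <- function(i0) i0 + 1L  # 0-based codon start -> 1-based
  # search upstream for ATG, stopping at an in-frame stop
  stops <- c("TAA", "TAG", "TGA")
  start0 <- region_start
  found_atg <- FALSE
  i <- region_start
  while (i >= 0L) {
    cod <- substr(seq, codon_start_1b(i), codon_start_1b(i) + 2L)
    if (cod %in% stops && i < region_start) break
    if (cod == "ATG") { start0 <- i; found_atg <- TRUE; break }
    i <- i - 3L
  }
  # forward to the first in-frame stop at/after region_end
  end0 <- NA_integer_
  j <- start0
  while (j + 3L <= n) {
    cod <- substr(seq, codon_start_1b(j), codon_start_1b(j) + 2L)
    if (cod %in% stops && j >= start0 + 3L) { end0 <- j + 3L; break }
    j <- j + 3L
  }
  has_stop <- !is.na(end0)
  if (!has_stop) end0 <- start0 + 3L * ((n - start0) %/% 3L)
  ncod <- (end0 - start0) %/% 3L - if (has_stop) 1L else 0L
  prot <- if (ncod > 0) {
    at <- start0 + 3L * (seq_len(ncod) - 1L) + 1L
    paste(.translate_codons(substring(seq, at, at + 2L)), collapse = "")
  } else ""
  list(start = start0, end = end0, frame = frame, protein = prot,
       complete = found_atg && has_stop)
}

#' Call the coding sequence of a contig
#'
#' Two routes, mirroring how curated transcriptome CDS sets are built:
#' \describe{
#'   \item{similarity}{when a hit with query coordinates exists, the best such
#'     hit (highest bitscore, then lowest e-value) anchors the CDS: its aligned
#'     region is extended in-frame to the ATG at or upstream of the region and
#'     to the next stop codon. The record is complete only when both ends were
#'     found.}
#'   \item{orf_signal}{otherwise the longest ORF of the contig is taken, and
#'     emitted only if its protein carries a positive signal-peptide call —
#'     unknown proteins are only trusted when they look secreted. Ties for
#'     longest break toward the most 5' start on the plus strand.}
#' }
#'
#' @param contig_id contig id.
#' @param sequence the contig's nucleotide sequence.
#' @param hits data.frame of hits for this contig (may be NULL/empty); the
#'   similarity route uses rows with `q_start`/`q_end`.
#' @param signal_calls named logical vector: signal-peptide call per contig id
#'   (externally produced, e.g. SignalP-class software).
#' @param min_aa minimum protein length for the ORF route.
#' @return one-row data.frame `contig_id`, `start`, `end`, `strand`, `frame`,
#'   `protein`, `complete`, `route`, `signal_peptide`, or NULL when neither
#'   route yields a candidate.
#' @export
call_cds <- function(contig_id, sequence, hits = NULL,
                     signal_calls = logical(), min_aa = 50) {
  seq <- toupper(sequence)
  usable <- !is.null(hits) && nrow(hits) > 0L &&
    all(c("q_start", "q_end") %in% names(hits)) &&
    any(!is.na(hits$q_start) & !is.na(hits$q_end))
  if (usable) {
    h <- hits[!is.na(hits$q_start) & !is.na(hits$q_end), ]
    h <- h[order(-h$bitscore, h$evalue), ][1L, ]
    minus <- h$q_start > h$q_end
    if (minus) {
      n <- nchar(seq)
      s <- .revcomp(seq)
      ext <- .extend_to_cds(s, n - h$q_start, n - h$q_end)
      res <- data.frame(contig_id = contig_id,
                        start = n - ext$end, end = n - ext$start,
                        strand = "-", frame = ext$frame,
                        protein = ext$protein, complete = ext$complete)
    } else {
      ext <- .extend_to_cds(seq, h$q_start, h$q_end)
      res <- data.frame(contig_id = contig_id,
                        start = ext$start, end = ext$end,
                        strand = "+", frame = ext$frame,
                        protein = ext$protein, complete = ext$complete)
    }
    res$route <- "similarity"
    res$signal_peptide <- isTRUE(unname(signal_calls[contig_id]))
    return(res)
  }
  orfs <- find_orfs(seq, min_aa = min_aa, contig_id = contig_id)
  if (nrow(orfs) == 0L) return(NULL)
  orfs <- orfs[order(-(nchar(orfs$protein)), orfs$start), ]
  best <- orfs[1L, ]
  if (!isTRUE(unname(signal_calls[contig_id]))) return(NULL)
  best$route <- "orf_signal"
  best$signal_peptide <- TRUE
  rownames(best) <- NULL
  best
}

#' Best-hit coverage filter
#'
#' Keeps hits whose subject coverage strictly exceeds the threshold; used to
#' select contigs that span (essentially) the full length of their best
#' protein match.
#'
#' @param hit one-row data.frame (or list) with a `coverage_frac` field.
#' @param threshold strict coverage threshold (default 0.90).
#' @return logical.
#' @export
coverage_filter <- function(hit, threshold = 0.90) {
  cv <- hit$coverage_frac
  if (is.null(cv) || length(cv) != 1L || is.na(cv))
    stop("hit has no coverage_frac; cannot apply the coverage filter")
  cv > threshold
}

#' Crude N-terminal signal-peptide heuristic (non-predictive stub)
#'
#' Flags proteins whose first 30 residues contain a run of at least 8
#' hydrophobic residues (AILMFWVC) — the h-region signature. This is a
#' self-containment device for synthetic tests only; it has none of the
#' discriminative power of real signal-peptide predictors and must not be
#' used for annotation.
#'
#' @param protein amino-acid string(s).
#' @return logical vector.
#' @export
signal_stub <- function(protein) {
  grepl("[AILMFWVC]{8,}", substr(protein, 1L, 30L))
}
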