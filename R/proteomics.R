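#' Match identified peptides against deduced proteins
#'
#' Every occurrence of every peptide in every protein is reported (a peptide
#' repeated within one protein yields one record per occurrence). Matching is
#' exact by default; `il_equivalent = TRUE` treats isoleucine and leucine as
#' interchangeable, since they are isobaric in MS.
#'
#' @param proteome named character vector of protein sequences (or a
#'   [Biostrings::AAStringSet]).
#' @param peptides data.frame with columns `peptide` and `fraction_id` (gel
#'   band of the identification).
#' @param il_equivalent treat I and L as the same residue.
#' @return data.frame `protein_id`, `peptide`, `fraction_id`, `start`, `end`
#'   (0-based half-open on the protein).
#' @export
match_peptides <- function(proteome, peptides, il_equivalent = FALSE) {
  proteome <- stats::setNames(as.character(proteome), names(proteome))
  empty <- data.frame(protein_id = character(), peptide = character(),
                      fraction_id = character(), start = integer(),
                      end = integer())
  if (!length(proteome) || !nrow(peptides)) return(empty)
  if (any(!nzchar(peptides$peptide))) stop("empty peptide sequence")
  key <- function(x) if (il_equivalent) chartr("I", "L", x) else x
  prot_k <- key(proteome)
  rows <- list()
  for (i in seq_len(nrow(peptides))) {
    pep <- peptides$peptide[i]
    pk <- key(pep)
    for (pid in names(proteome)) {
      m <- gregexpr(pk, prot_k[[pid]], fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      for (s in as.integer(m))
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = pid, peptide = pep,
          fraction_id = as.character(peptides$fraction_id[i]),
          start = s - 1L, end = s - 1L + nchar(pep))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# union length of 0-based half-open intervals
.interval_union <- function(start, end) {
  if (!length(start)) return(0L)
  r <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(IRanges::width(r))
}

#' Confirm deduced proteins from matched peptide evidence
#'
#' A deduced protein is confirmed when at least `min_ions` distinct peptide
#' sequences ("ions") match it; a peptide seen in several gel bands counts
#' once toward `n_ions` but each observation counts toward
#' `n_fragments_total`. Coverage is the number of residues covered by the
#' union of all matched intervals — total amino acid residues without
#' duplication. The best gel fraction is the one whose own matches cover the
#' most residues (ties break to the lexicographically smallest fraction id)
#' and is only assigned for confirmed proteins.
#'
#' @param evidence data.frame from [match_peptides()].
#' @param min_ions distinct-peptide threshold for confirmation (default 2).
#' @return data.frame `protein_id`, `n_ions`, `n_fragments_total`,
#'   `coverage_residues`, `best_fraction`, `confirmed`.
#' @export
confirm <- function(evidence, min_ions = 2) {
  stopifnot(min_ions >= 1)
  if (!nrow(evidence))
    return(data.frame(protein_id = character(), n_ions = integer(),
                      n_fragments_total = integer(),
                      coverage_residues = integer(),
                      best_fraction = character(), confirmed = logical()))
  res <- lapply(split(evidence, evidence$protein_id), function(ev) {
    n_ions <- length(unique(ev$peptide))
    frac_cov <- vapply(split(ev, ev$fraction_id),
                       function(e) .interval_union(e$start, e$end), integer(1))
    fr <- names(frac_cov)[order(-frac_cov, names(frac_cov))][1L]
    confirmed <- n_ions >= min_ions
    data.frame(protein_id = ev$protein_id[1L], n_ions = n_ions,
               n_fragments_total = nrow(ev),
               coverage_residues = .interval_union(ev$start, ev$end),
               best_fraction = if (confirmed) fr else NA_character_,
               confirmed = confirmed)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$protein_id), , drop = FALSE]
}
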