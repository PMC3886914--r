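#' Scan a protein for the peritrophin chitin-binding domain
#'
#' The domain is a six-cysteine motif with characteristic spacings,
#' `C X15-17 C X5-6 C X9 C X12 C X6-7 C`, where X is any residue (including,
#' by default, cysteine itself; `strict_gaps = TRUE` forbids C inside gaps).
#' Every match at every start position and every admissible gap combination is
#' reported, overlaps included, so multi-domain peritrophins yield one row per
#' domain instance.
#'
#' The scan enumerates the twelve fixed-length spacing combinations as
#' zero-width lookahead regular expressions, which finds overlapping starts.
#'
#' @param protein amino-acid string (20-letter alphabet plus X).
#' @param protein_id optional id copied into the result.
#' @param strict_gaps forbid cysteine inside the inter-cysteine gaps.
#' @return data.frame `protein_id`, `start`, `end` (0-based half-open),
#'   `cys_positions` (comma-joined 0-based indices), `spacings` (comma-joined
#'   gap lengths), sorted by `(start, end, spacings)`.
#' @export
scan_cbd <- function(protein, protein_id = NA_character_, strict_gaps = FALSE) {
  gaps <- expand.grid(g1 = 15:17, g2 = 5:6, g3 = 9L, g4 = 12L, g5 = 6:7)
  x <- if (strict_gaps) "[^C]" else "."
  rows <- list()
  if (nzchar(protein)) {
    for (k in seq_len(nrow(gaps))) {
      g <- as.integer(gaps[k, ])
      pat <- sprintf("(?=C%s{%d}C%s{%d}C%s{%d}C%s{%d}C%s{%d}C)",
                     x, g[1], x, g[2], x, g[3], x, g[4], x, g[5])
      m <- gregexpr(pat, protein, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      for (s1 in as.integer(m)) {          # 1-based start of the first C
        start0 <- s1 - 1L
        cys <- start0 + cumsum(c(0L, g + 1L))
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = protein_id, start = start0,
          end = start0 + 6L + sum(g),
          cys_positions = paste(cys, collapse = ","),
          spacings = paste(g, collapse = ","))
      }
    }
  }
  if (!length(rows))
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), cys_positions = character(),
                      spacings = character()))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$start, out$end, out$spacings), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mucin-type Ser/Thr richness score
#'
#' Vertebrate-type mucins are Ser/Thr-rich, heavily O-glycosylated secreted
#' proteins; since glycosylation-site prediction is upstream software, the
#' implementable proxy is Ser+Thr density. Reports the whole-protein S/T
#' fraction, the maximum S/T count over any window of the given length
#' (candidate glycosylation cluster size), and a mucin-like flag.
#'
#' @param protein amino-acid string.
#' @param protein_id optional id.
#' @param window sliding window length in residues (whole protein if shorter).
#' @param st_threshold whole-protein S/T fraction at or above which the
#'   protein is flagged mucin-like (default 0.30, a package default, not a
#'   literature constant).
#' @return one-row data.frame `protein_id`, `st_fraction`, `candidate_sites`,
#'   `is_mucin_like`.
#' @export
mucin_score <- function(protein, protein_id = NA_character_, window = 100,
                        st_threshold = 0.30) {
  stopifnot(window >= 1)
  n <- nchar(protein)
  if (n == 0L)
    return(data.frame(protein_id = protein_id, st_fraction = 0,
                      candidate_sites = 0L, is_mucin_like = FALSE))
  is_st <- as.integer(strsplit(protein, "")[[1]] %in% c("S", "T"))
  frac <- sum(is_st) / n
  w <- min(window, n)
  cs <- cumsum(c(0L, is_st))
  win_counts <- cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]
  data.frame(protein_id = protein_id, st_fraction = frac,
             candidate_sites = max(win_counts),
             is_mucin_like = frac >= st_threshold)
}
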