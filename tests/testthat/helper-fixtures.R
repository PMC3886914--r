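# shared builders and independent oracles

toy_catalog <- function() {
  catalog(
    libraries = data.frame(library_id = c("AM", "PM"),
                           total_reads = c(1000, 1000)),
    contigs = data.frame(contig_id = c("X", "Y"), length_nt = c(400L, 600L),
                         AM = c(40L, 5L), PM = c(4L, 5L))
  )
}

write_counts_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random protein with elevated cysteine content so CBD-like matches occur
random_protein <- function(n, c_weight = 6) {
  aa <- c("A", "C", "D", "E", "G", "K", "L", "R", "S", "T", "V")
  w <- rep(1, length(aa)); w[aa == "C"] <- c_weight
  paste(sample(aa, n, replace = TRUE, prob = w), collapse = "")
}

# brute-force CBD oracle: enumerate all six cysteine positions under the
# spacing constraints, independent of the regex scan
cbd_oracle <- function(protein) {
  ch <- strsplit(protein, "")[[1]]
  cpos <- which(ch == "C")  # 1-based
  out <- list()
  for (c1 in cpos) for (g1 in 15:17) {
    c2 <- c1 + g1 + 1L
    if (c2 > length(ch) || ch[c2] != "C") next
    for (g2 in 5:6) {
      c3 <- c2 + g2 + 1L
      if (c3 > length(ch) || ch[c3] != "C") next
      c4 <- c3 + 10L
      if (c4 > length(ch) || ch[c4] != "C") next
      c5 <- c4 + 13L
      if (c5 > length(ch) || ch[c5] != "C") next
      for (g5 in 6:7) {
        c6 <- c5 + g5 + 1L
        if (c6 > length(ch) || ch[c6] != "C") next
        out[[length(out) + 1L]] <- data.frame(
          start = c1 - 1L, end = c6,
          spacings = paste(c(g1, g2, 9L, 12L, g5), collapse = ","))
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      spacings = character()))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$start, res$end, res$spacings), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# interval-union oracle by residue enumeration
union_oracle <- function(start, end, n) {
  covered <- logical(n)
  for (i in seq_along(start)) covered[(start[i] + 1L):end[i]] <- TRUE
  sum(covered)
}

# a CBD instance with the given gaps, embedded in polyalanine
cbd_instance <- function(gaps, pad_left = 3, pad_right = 3) {
  paste0(strrep("A", pad_left),
         paste0("C", paste(vapply(gaps, function(g) strrep("A", g),
                                  character(1)),
                           "C", sep = "", collapse = "")),
         strrep("A", pad_right))
}
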