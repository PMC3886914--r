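#' Simulate a contig-by-library read ledger
#'
#' Baseline per-contig abundances are drawn from a symmetric Dirichlet (small
#' concentration gives the long-tailed abundance profile of EST libraries);
#' each library's counts are then multinomial with the declared total, so
#' column sums conserve the totals exactly, as in a real read-tracked
#' assembly. A designated fraction of contigs is spiked: their probability is
#' multiplied by `fold` in the numerator (spiked) libraries.
#'
#' Two renormalization conventions are available. `"preserve"` (default)
#' scales only the unspiked contigs down, so a spiked contig's realized
#' enrichment is exactly `fold` and the recorded truth is what the data show;
#' `"flat"` divides every probability by the common normalizing constant,
#' which compresses the realized enrichment below `fold` when the spiked mass
#' is non-negligible.
#'
#' @param n_contigs number of contigs.
#' @param library_totals named vector of per-library read totals (all > 0).
#' @param spike_libs library ids in which spiked contigs are enriched.
#' @param spike_fraction fraction of contigs spiked, in [0,1].
#' @param fold spike fold change (>= 1).
#' @param concentration symmetric Dirichlet concentration (default 0.5).
#' @param seed integer seed.
#' @param renormalize `"preserve"` or `"flat"` (see above).
#' @param length_range contig length range, nt (uniform; default 150-3000).
#' @return list with `catalog` (a [catalog]) and `truth` (list: `contig_ids`,
#'   `spiked` data.frame `contig_id`, `fold`, `baseline_p`; `spike_libs`).
#' @export
simulate_catalog <- function(n_contigs, library_totals, spike_libs = character(),
                             spike_fraction = 0, fold = 1, concentration = 0.5,
                             seed = 1, renormalize = c("preserve", "flat"),
                             length_range = c(150L, 3000L)) {
  renormalize <- match.arg(renormalize)
  stopifnot(n_contigs >= 1, spike_fraction >= 0, spike_fraction <= 1, fold >= 1)
  if (any(library_totals <= 0)) stop("library totals must be positive")
  if (length(setdiff(spike_libs, names(library_totals))))
    stop("spike_libs must be declared libraries")
  set.seed(seed)
  g <- stats::rgamma(n_contigs, shape = concentration)
  g[g <= 0] <- .Machine$double.xmin
  p <- g / sum(g)
  ids <- sprintf("ctg%05d", seq_len(n_contigs))

  n_spiked <- round(spike_fraction * n_contigs)
  spiked_idx <- if (n_spiked > 0) sort(sample.int(n_contigs, n_spiked)) else integer()
  q <- p
  if (length(spiked_idx) && fold > 1) {
    m <- sum(p[spiked_idx])
    if (renormalize == "preserve") {
      if (fold * m >= 1)
        stop("spiked mass * fold >= 1; reduce spike_fraction/fold or use 'flat'")
      q[spiked_idx] <- fold * p[spiked_idx]
      q[-spiked_idx] <- p[-spiked_idx] * (1 - fold * m) / (1 - m)
    } else {
      q[spiked_idx] <- fold * p[spiked_idx]
      q <- q / sum(q)
    }
  }

  counts <- vapply(names(library_totals), function(lib) {
    prob <- if (lib %in% spike_libs) q else p
    as.integer(stats::rmultinom(1, size = library_totals[[lib]], prob = prob))
  }, integer(n_contigs))
  lengths <- sample(seq.int(length_range[1], length_range[2]), n_contigs,
                    replace = TRUE)
  contigs <- data.frame(contig_id = ids, length_nt = lengths, counts,
                        check.names = FALSE)
  cat <- catalog(libraries = data.frame(library_id = names(library_totals),
                                        total_reads = as.numeric(library_totals)),
                 contigs = contigs)
  list(catalog = cat,
       truth = list(contig_ids = ids,
                    spiked = data.frame(contig_id = ids[spiked_idx],
                                        fold = rep(fold, length(spiked_idx)),
                                        baseline_p = p[spiked_idx]),
                    baseline_p = p, spike_libs = spike_libs))
}

# background amino-acid frequencies (rounded database composition)
.aa_freq <- c(A = 8.3, R = 5.6, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.7,
              G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
              P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)

# codons per amino acid, stops excluded
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Simulate a proteome with planted features and matching contigs
#'
#' Proteins are sampled at background residue frequencies. With probability
#' `motif_rate` a valid chitin-binding-domain spacing instance (six cysteines)
#' is planted at a recorded position; with probability `signal_rate` the
#' protein is flagged signal-peptide positive and given an N-terminal
#' hydrophobic stretch. Each protein is reverse-translated (random synonymous
#' codons) into a contig carrying the ATG...stop frame, an upstream in-frame
#' stop to terminate spurious upstream starts, random flanks, and a random
#' strand, so ORF finding can be exercised end to end.
#'
#' @param n_proteins number of proteins.
#' @param motif_rate,signal_rate planting probabilities in [0,1].
#' @param seed integer seed.
#' @param len_range protein length range in residues (default 80-600).
#' @return list with `proteins` (named character), `contigs` (named character,
#'   ids `<protein_id>_ctg`), `signal` (named logical), `truth` (list:
#'   `planted_motifs` data.frame `protein_id`, `start`, `spacings`; `cds`
#'   data.frame `protein_id`, `contig_id`, `start`, `end`, `strand`).
#' @export
simulate_proteome <- function(n_proteins, motif_rate = 0, signal_rate = 0,
                              seed = 1, len_range = c(80L, 600L)) {
  stopifnot(motif_rate >= 0, motif_rate <= 1, signal_rate >= 0, signal_rate <= 1)
  set.seed(seed)
  aa <- names(.aa_freq)
  w <- .aa_freq / sum(.aa_freq)
  ct <- .codon_table()
  proteins <- character(n_proteins)
  contigs <- character(n_proteins)
  signal <- logical(n_proteins)
  pids <- sprintf("prot%04d", seq_len(n_proteins))
  motifs <- list(); cds <- list()
  for (i in seq_len(n_proteins)) {
    len <- sample(seq.int(len_range[1], len_range[2]), 1L)
    res <- c("M", sample(aa, len - 1L, replace = TRUE, prob = w))
    if (stats::runif(1) < signal_rate) {
      signal[i] <- TRUE
      res[2:13] <- sample(c("L", "A", "V", "I", "F"), 12L, replace = TRUE)
    }
    if (stats::runif(1) < motif_rate && len >= 70L) {
      g <- c(sample(15:17, 1L), sample(5:6, 1L), 9L, 12L, sample(6:7, 1L))
      span <- 6L + sum(g)
      start0 <- sample(seq.int(14L, len - span), 1L)   # 0-based, after N-term
      cys <- start0 + cumsum(c(0L, g + 1L))
      res[cys + 1L] <- "C"
      motifs[[length(motifs) + 1L]] <- data.frame(
        protein_id = pids[i], start = start0,
        spacings = paste(g, collapse = ","))
    }
    proteins[i] <- paste(res, collapse = "")
    codons <- vapply(res, function(a) sample(ct[[a]], 1L), character(1))
    codons[1] <- "ATG"
    orf <- paste0(paste(codons, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1L))
    rand_nt <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                                 collapse = "")
    f5 <- paste0(rand_nt(3L * sample(0:20, 1L)), "TAA")
    f3 <- rand_nt(sample(0:60, 1L))
    plus <- paste0(f5, orf, f3)
    s0 <- nchar(f5); e0 <- s0 + nchar(orf)
    if (stats::runif(1) < 0.5) {
      contigs[i] <- plus
      cds[[length(cds) + 1L]] <- data.frame(protein_id = pids[i],
                                            contig_id = paste0(pids[i], "_ctg"),
                                            start = s0, end = e0, strand = "+")
    } else {
      contigs[i] <- .revcomp(plus)
      n <- nchar(plus)
      cds[[length(cds) + 1L]] <- data.frame(protein_id = pids[i],
                                            contig_id = paste0(pids[i], "_ctg"),
                                            start = n - e0, end = n - s0,
                                            strand = "-")
    }
  }
  names(proteins) <- pids
  names(contigs) <- paste0(pids, "_ctg")
  names(signal) <- pids
  list(proteins = proteins, contigs = contigs, signal = signal,
       truth = list(planted_motifs = do.call(rbind, c(motifs, list(NULL))),
                    cds = do.call(rbind, cds)))
}

#' Simulate a homology hit table with recoverable categories
#'
#' Assigns each contig a true functional category (uniformly over the
#' vocabulary's categories) and emits one hit per contig whose description
#' carries a word of that category at an early token position. With
#' probability `noise_rate` a decoy word from a different category is appended
#' at a later token position, so position weighting is what keeps
#' classification accurate.
#'
#' @param contig_ids contigs to annotate.
#' @param vocab a [read_vocab()] vocabulary.
#' @param noise_rate decoy probability in [0,1].
#' @param seed integer seed.
#' @param drop_rate probability a contig gets no hits at all (true category
#'   `"Unknown"`); default 0.
#' @return list with `hits` (data.frame in [read_hits()] layout) and
#'   `category_of` (named character: true category per contig).
#' @export
simulate_hits <- function(contig_ids, vocab, noise_rate = 0, seed = 1,
                          drop_rate = 0) {
  stopifnot(inherits(vocab, "vocabulary"),
            noise_rate >= 0, noise_rate <= 1, drop_rate >= 0, drop_rate <= 1)
  set.seed(seed)
  cats <- setdiff(vocab$categories, c("Unknown", "Unknown, conserved"))
  if (!length(cats)) stop("vocabulary has no assignable categories")
  filler <- c("putative", "predicted", "isoform", "partial", "homolog")
  truth <- stats::setNames(sample(cats, length(contig_ids), replace = TRUE),
                           contig_ids)
  rows <- list()
  for (id in contig_ids) {
    if (stats::runif(1) < drop_rate) { truth[[id]] <- "Unknown"; next }
    word <- sample(vocab$entries$word[vocab$entries$category == truth[[id]]], 1L)
    desc <- paste(c(word, sample(filler, 2L)), collapse = " ")
    if (stats::runif(1) < noise_rate) {
      other <- sample(setdiff(cats, truth[[id]]), 1L)
      decoy <- sample(vocab$entries$word[vocab$entries$category == other], 1L)
      desc <- paste(desc, decoy)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = id, db = sample(vocab$db_precedence, 1L),
      subject_id = paste0("sbj_", id), bitscore = round(stats::runif(1, 60, 400)),
      evalue = 10^(-stats::runif(1, 10, 80)), identity_frac = NA_real_,
      coverage_frac = NA_real_, description = desc)
  }
  list(hits = if (length(rows)) do.call(rbind, rows) else
         data.frame(query_id = character(), db = character(),
                    subject_id = character(), bitscore = numeric(),
                    evalue = numeric(), identity_frac = numeric(),
                    coverage_frac = numeric(), description = character()),
       category_of = truth)
}

#' Simulate tryptic-like peptide identifications from a proteome
#'
#' Samples non-overlapping peptides of 7-15 residues per protein, preferring
#' peptides that end at K or R (tryptic-like), and assigns each to a random
#' gel fraction. Proteins shorter than the minimum peptide are skipped with a
#' warning.
#'
#' @param proteome named character vector of protein sequences.
#' @param ions_per_protein peptides sampled per protein (>= 0).
#' @param seed integer seed.
#' @param fractions pool of gel-fraction labels.
#' @return list with `peptides` (data.frame `peptide`, `fraction_id`) and
#'   `truth` (data.frame `protein_id`, `peptide`, `start`, `end`).
#' @export
simulate_peptides <- function(proteome, ions_per_protein = 2, seed = 1,
                              fractions = paste0("F", 1:6)) {
  stopifnot(ions_per_protein >= 0)
  set.seed(seed)
  rows <- list()
  for (pid in names(proteome)) {
    prot <- proteome[[pid]]
    n <- nchar(prot)
    if (n < 7L) {
      warning("protein ", pid, " shorter than the minimum peptide; skipped")
      next
    }
    if (ions_per_protein == 0) next
    chars <- strsplit(prot, "")[[1]]
    kr_ends <- which(chars %in% c("K", "R"))
    kr_ends <- kr_ends[kr_ends >= 7L]
    taken <- integer()
    got <- 0L
    for (try in seq_len(200L)) {
      if (got >= ions_per_protein) break
      len <- sample(7:15, 1L)
      end <- if (length(kr_ends) && stats::runif(1) < 0.9)
        sample(rep(kr_ends, 2L), 1L) else sample(seq.int(len, n), 1L)
      start <- end - len + 1L
      if (start < 1L) next
      span <- start:end
      if (any(span %in% taken)) next
      taken <- c(taken, span)
      got <- got + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, peptide = substr(prot, start, end),
        fraction_id = sample(fractions, 1L),
        start = start - 1L, end = end)
    }
    if (got < ions_per_protein)
      warning("protein ", pid, ": only ", got, " of ", ions_per_protein,
              " peptides placed")
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), peptide = character(),
               fraction_id = character(), start = integer(), end = integer())
  list(peptides = truth[, c("peptide", "fraction_id")],
       truth = truth[, c("protein_id", "peptide", "start", "end")])
}
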