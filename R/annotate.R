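#' Read a homology hit table
#'
#' Tab-separated, BLAST outfmt-6-like with a database tag and the subject
#' description: `query_id, db, subject_id, bitscore, evalue, identity,
#' coverage, description`, optionally followed by `q_start, q_end` (0-based
#' half-open query coordinates on the plus strand; a start greater than the
#' end marks a minus-strand alignment, BLAST style). `identity` and `coverage`
#' are fractions in [0,1] and may be empty.
#'
#' @param path hits TSV path. A header line is detected by the literal
#'   `query_id` in the first field and skipped.
#' @return data.frame of hits.
#' @export
read_hits <- function(path) {
  base <- c("query_id", "db", "subject_id", "bitscore", "evalue",
            "identity_frac", "coverage_frac", "description")
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && startsWith(first, "query_id")) 1L else 0L
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          skip = skip, stringsAsFactors = FALSE)
  if (ncol(df) == length(base)) {
    names(df) <- base
  } else if (ncol(df) == length(base) + 2L) {
    names(df) <- c(base, "q_start", "q_end")
  } else stop("hits table must have 8 or 10 columns, got ", ncol(df))
  if (any(df$bitscore < 0, na.rm = TRUE) || any(df$evalue < 0, na.rm = TRUE))
    stop("bitscore and evalue must be non-negative")
  df
}

#' Read or build a keyword vocabulary
#'
#' The vocabulary maps lowercase words (or multi-word phrases) found in hit
#' descriptions to functional categories, each with a positive weight. The
#' original curated vocabulary behind the reference dataset was never
#' published; the default shipped with this package is a reconstruction from
#' the class labels of the published summary tables with common synonyms, and
#' should be replaced by a curated file for serious annotation work.
#'
#' @param path a TSV `word<TAB>category<TAB>weight` (weight optional,
#'   default 1), or NULL for the shipped default.
#' @param db_precedence database tags in decreasing trust order; hits from the
#'   r-th tag (0-based) are down-weighted by `1/(1+r)`, and unknown tags rank
#'   after all listed ones.
#' @return an object of class `vocabulary`: list with `entries` (data.frame
#'   `word`, `category`, `weight`), `categories`, `db_precedence`.
#' @export
read_vocab <- function(path = NULL,
                       db_precedence = c("KOG", "CDD", "SwissProt", "GO", "NR")) {
  if (is.null(path))
    path <- system.file("extdata", "default_vocab.tsv",
                        package = "compartscan", mustWork = TRUE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("word", "category") %in% names(df)))
    stop("vocabulary needs 'word' and 'category' columns")
  if (is.null(df$weight)) df$weight <- 1
  df$word <- tolower(df$word)
  if (any(df$weight <= 0)) stop("vocabulary weights must be positive")
  if (anyDuplicated(df[, c("word", "category")]))
    stop("duplicate word within a category")
  structure(list(entries = df[, c("word", "category", "weight")],
                 categories = sort(unique(df$category)),
                 db_precedence = db_precedence),
            class = "vocabulary")
}

.tokenize <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# position of the first occurrence of a word or phrase in a token vector,
# 0-based; NA when absent
.first_token_pos <- function(word_tokens, tokens) {
  k <- length(word_tokens)
  n <- length(tokens)
  if (k == 0L || n < k) return(NA_integer_)
  hit <- which(tokens == word_tokens[1L])
  for (i in hit) {
    if (i + k - 1L <= n && all(tokens[i:(i + k - 1L)] == word_tokens))
      return(i - 1L)
  }
  NA_integer_
}

#' Classify one contig from its hit descriptions
#'
#' Each description is lowercased and tokenized on non-alphanumeric
#' characters. A vocabulary word found in a description contributes
#' `weight * 1/(1 + first token index) * 1/(1 + database rank)` to its
#' category; the category with the highest total wins. A contig with no hits
#' at all is `"Unknown"`; one whose hits match no vocabulary word is
#' `"Unknown, conserved"` — conserved proteins with no assignable function.
#' Score ties break toward the category whose best-contributing hit has the
#' lower e-value, then lexicographically.
#'
#' @param contig_id id of the contig (hits are assumed to belong to it).
#' @param hits data.frame as from [read_hits()] (may be empty).
#' @param vocab a [read_vocab()] vocabulary.
#' @return list with `contig_id`, `category`, `score`, and `evidence`
#'   (data.frame `db`, `word`, `category`, `token_pos`, `contribution`,
#'   `evalue`).
#' @export
classify <- function(contig_id, hits, vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  if (!length(vocab$categories)) stop("vocabulary category set is empty")
  empty_ev <- data.frame(db = character(), word = character(),
                         category = character(), token_pos = integer(),
                         contribution = numeric(), evalue = numeric())
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(contig_id = contig_id, category = "Unknown", score = 0,
                evidence = empty_ev))

  prec <- vocab$db_precedence
  word_tok <- strsplit(vocab$entries$word, "[^a-z0-9]+")
  ev <- vector("list", nrow(hits))
  for (h in seq_len(nrow(hits))) {
    toks <- .tokenize(hits$description[h])
    if (!length(toks)) next
    r <- match(hits$db[h], prec)
    if (is.na(r)) r <- length(prec) + 1L else r <- r - 1L
    db_factor <- 1 / (1 + r)
    pos <- vapply(word_tok, .first_token_pos, integer(1), tokens = toks)
    found <- which(!is.na(pos))
    if (length(found))
      ev[[h]] <- data.frame(db = hits$db[h],
                            word = vocab$entries$word[found],
                            category = vocab$entries$category[found],
                            token_pos = pos[found],
                            contribution = vocab$entries$weight[found] *
                              (1 / (1 + pos[found])) * db_factor,
                            evalue = hits$evalue[h])
  }
  ev <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  if (is.null(ev) || nrow(ev) == 0L)
    return(list(contig_id = contig_id, category = "Unknown, conserved",
                score = 0, evidence = empty_ev))

  scores <- tapply(ev$contribution, ev$category, sum)
  top <- max(scores)
  cands <- names(scores)[scores >= top - 1e-12]
  if (length(cands) > 1L) {
    # best-contributing hit's e-value per candidate, then lexicographic
    best_e <- vapply(cands, function(cc) {
      sub <- ev[ev$category == cc, ]
      sub$evalue[which.max(sub$contribution)]
    }, numeric(1))
    cands <- cands[order(best_e, cands)]
  }
  list(contig_id = contig_id, category = cands[[1L]], score = unname(top),
       evidence = ev[order(-ev$contribution), ])
}

#' Classify every contig of a hit table
#'
#' @param contig_ids contigs to classify; those absent from `hits` come out
#'   `"Unknown"`.
#' @param hits data.frame as from [read_hits()].
#' @param vocab a [read_vocab()] vocabulary.
#' @return data.frame `contig_id`, `category`, `score`.
#' @export
classify_contigs <- function(contig_ids, hits, vocab) {
  split_hits <- if (nrow(hits)) split(hits, hits$query_id) else list()
  res <- lapply(contig_ids, function(id)
    classify(id, split_hits[[id]], vocab))
  data.frame(contig_id = vapply(res, `[[`, character(1), "contig_id"),
             category = vapply(res, `[[`, character(1), "category"),
             score = vapply(res, `[[`, numeric(1), "score"))
}

#' Assign the organism origin of a coding sequence
#'
#' Compares the best blastp bitscore of a deduced protein against each origin
#' database (host/invertebrate, vertebrate, bacteria, virus). The top-scoring
#' origin is assigned only when it beats the runner-up by a bitscore ratio
#' strictly greater than `ratio_gate` AND its own e-value is below
#' `evalue_gate`; otherwise the call is `"ambiguous"` (such sequences stay
#' under the host default in summaries). A single available origin is returned
#' as-is.
#'
#' @param best_scores named list (or data.frame with rownames) mapping each
#'   origin tag to `c(bitscore, evalue)`.
#' @param ratio_gate top/second bitscore ratio gate (strict; default 1.25).
#' @param evalue_gate e-value gate on the top origin (strict; default 1e-15).
#' @return the winning origin tag, or `"ambiguous"`.
#' @export
assign_origin <- function(best_scores, ratio_gate = 1.25, evalue_gate = 1e-15) {
  if (!length(best_scores)) stop("at least one origin entry is required")
  tags <- names(best_scores)
  bits <- vapply(best_scores, function(x) as.numeric(x[[1]]), numeric(1))
  evs  <- vapply(best_scores, function(x) as.numeric(x[[2]]), numeric(1))
  o <- order(bits, decreasing = TRUE)
  if (bits[o[1]] <= 0) stop("top bitscore must be positive")
  if (length(tags) == 1L) return(tags)
  ratio <- bits[o[1]] / bits[o[2]]
  if (ratio > ratio_gate && evs[o[1]] < evalue_gate) tags[o[1]] else "ambiguous"
}

#' Per-class arithmetic of a functional summary table
#'
#' Given per-class contig and read counts and the scope's total read count,
#' computes the two derived columns of the published-style summary tables:
#' reads per contig and percent of scope reads, both to one decimal.
#'
#' Rounding is half-away-from-zero (the convention of the published tables),
#' not R's banker's rounding: 139.25 prints as 139.3.
#'
#' @param n_contigs,n_reads integer vectors, one entry per class.
#' @param scope_total total reads in the scope (denominator of the percent).
#' @return data.frame `n_contigs`, `n_reads`, `reads_per_contig`, `pct_reads`.
#' @export
class_table_stats <- function(n_contigs, n_reads, scope_total) {
  stopifnot(length(n_contigs) == length(n_reads), scope_total >= 0)
  pct <- if (scope_total > 0) 100 * n_reads / scope_total else
    rep(0, length(n_reads))
  data.frame(n_contigs = n_contigs, n_reads = n_reads,
             reads_per_contig = round_half_up(ifelse(n_contigs > 0,
                                                     n_reads / n_contigs, 0), 1),
             pct_reads = round_half_up(pct, 1))
}

#' Round half away from zero
#'
#' Tabulation convention of the summary tables (0.25 -> 0.3), unlike base
#' [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Functional class summary of flagged contigs
#'
#' Builds a published-table-style summary over the contigs a contrast flags:
#' per category the number of member contigs, the numerator reads they hold,
#' reads per contig and the percent of the scope's reads, plus a total row.
#'
#' @param assignments data.frame `contig_id`, `category` (e.g. from
#'   [classify_contigs()]); must cover every flagged contig.
#' @param rows a [run_contrast()] result.
#' @param scope which flag defines table membership: `"over_table"` (default),
#'   `"over_interest"` or `"significant"`.
#' @return data.frame `category`, `n_contigs`, `n_reads`, `reads_per_contig`,
#'   `pct_reads`, categories in decreasing read order, final row `Total`.
#' @export
class_summary <- function(assignments, rows,
                          scope = c("over_table", "over_interest", "significant")) {
  scope <- match.arg(scope)
  member <- rows[rows[[scope]], c("contig_id", "a")]
  if (nrow(member) == 0L)
    return(data.frame(category = "Total", n_contigs = 0L, n_reads = 0,
                      reads_per_contig = 0, pct_reads = 0))
  cls <- assignments$category[match(member$contig_id, assignments$contig_id)]
  if (anyNA(cls))
    stop("flagged contig(s) without classification: ",
         paste(member$contig_id[is.na(cls)], collapse = ", "))
  n_contigs <- tapply(member$contig_id, cls, length)
  n_reads <- tapply(member$a, cls, sum)
  total <- sum(member$a)
  out <- data.frame(category = names(n_reads),
                    class_table_stats(as.integer(n_contigs),
                                      as.numeric(n_reads), total))
  out <- out[order(-out$n_reads, out$category), ]
  rbind(out,
        data.frame(category = "Total", n_contigs = nrow(member),
                   n_reads = total, reads_per_contig = NA_real_,
                   pct_reads = round(100, 1)))
}
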