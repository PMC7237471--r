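# Semi-global protein alignment layer used by the greedy-centroid clusterer.
# Scoring is a fixed simple scheme (match +1, mismatch -1, gap open -2,
# gap extend -1) with free end gaps, standing in for USEARCH's internal
# aligner at desk scale. Identity is matches / alignment columns.

aa_letters <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
}

simple_substitution_matrix <- function() {
  aa <- aa_letters()
  m <- matrix(-1L, length(aa), length(aa), dimnames = list(aa, aa))
  diag(m) <- 1L
  m["X", ] <- -1L  # ambiguous residue never counts as a match
  m[, "X"] <- -1L
  m
}

#' Pairwise semi-global alignment statistics
#'
#' Aligns two amino-acid sequences with free end gaps (overlap alignment)
#' under a fixed scoring scheme (match +1, mismatch -1, gap open -2, gap
#' extend -1) and reports identity as matching columns over alignment
#' columns, together with the aligned span of each sequence as a fraction of
#' its length. For dissimilar sequences the optimal overlap alignment can be
#' short (or empty, giving identity and coverage 0), which is why coverage
#' thresholds must accompany identity thresholds in clustering.
#'
#' @param a,b Amino-acid sequences (non-empty character scalars).
#' @return List with `identity`, `query_coverage` (span of `a`), and
#'   `target_coverage` (span of `b`), all in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  stats <- align_stats(Biostrings::AAStringSet(a), Biostrings::AAString(b),
                       nchar(a), nchar(b))
  as.list(stats[1L, ])
}

# Vectorised core: aligns each pattern against one subject.
align_stats <- function(patterns, subject, plens, slen) {
  aln <- Biostrings::pairwiseAlignment(
    patterns, subject, type = "overlap",
    substitutionMatrix = simple_substitution_matrix(),
    gapOpening = 2, gapExtension = 1
  )
  cols <- Biostrings::nchar(aln)
  matches <- Biostrings::nmatch(aln)
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  qspan <- pmax(Biostrings::end(p) - Biostrings::start(p) + 1L, 0L)
  sspan <- pmax(Biostrings::end(s) - Biostrings::start(s) + 1L, 0L)
  data.frame(
    identity = ifelse(cols > 0, matches / cols, 0),
    query_coverage = qspan / plens,
    target_coverage = sspan / slen
  )
}

# Alignment cache shared across greedy passes: reseeded runs realign the
# same protein pairs, so results are memoised by (query id, target id).
new_alignment_cache <- function() new.env(parent = emptyenv())

cached_align <- function(records, qids, tid, cache = NULL) {
  seqs <- setNames(records$sequence, records$id)
  lens <- setNames(records$length, records$id)
  if (is.null(cache)) {
    return(align_stats(Biostrings::AAStringSet(seqs[qids]),
                       Biostrings::AAString(seqs[[tid]]),
                       unname(lens[qids]), lens[[tid]]))
  }
  keys <- paste(qids, tid, sep = "\r")
  hit <- vapply(keys, exists, logical(1), envir = cache, inherits = FALSE)
  if (any(!hit)) {
    fresh <- align_stats(Biostrings::AAStringSet(seqs[qids[!hit]]),
                         Biostrings::AAString(seqs[[tid]]),
                         unname(lens[qids[!hit]]), lens[[tid]])
    for (k in seq_len(sum(!hit))) {
      assign(keys[!hit][k], as.numeric(fresh[k, ]), envir = cache)
    }
  }
  out <- t(vapply(keys, get, numeric(3), envir = cache, inherits = FALSE))
  data.frame(identity = out[, 1L], query_coverage = out[, 2L],
             target_coverage = out[, 3L])
}
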