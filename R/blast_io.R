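#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Parses the standard 12-column BLAST tabular layout
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) into a similarity-hit table. Coverage is not part of the
#' tabular output, so it is computed from the alignment spans and the
#' sequence lengths supplied in `length_lookup`:
#' query coverage `= 100 * (qend - qstart + 1) / qlen` and likewise for the
#' target. Coordinates are treated as 1-based inclusive; reverse-style
#' coordinates (`sstart > send`) are normalised by absolute span. The hit
#' rank within each query follows file order, which for native BLAST output
#' is descending score order.
#'
#' @param path Path to the tabular hit file.
#' @param length_lookup Named numeric vector of sequence lengths, keyed by
#'   sequence id; must cover every id in the file.
#' @return A hit `data.frame` with columns `query`, `target`, `identity`
#'   (percent), `query_coverage`, `target_coverage` (percent), `bitscore`,
#'   `rank` (1-based within query, file order), and `self` (query == target).
#' @export
read_blast_tab <- function(path, length_lookup) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || length(nf) == 0L) stop("hit file is empty: ", path)
  bad <- which(nf != 12L)
  if (length(bad) > 0L) {
    stop("malformed hit file (expected 12 tab-separated columns) at line ", bad[1L])
  }
  cols <- c("query", "target", "identity", "alen", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- read.table(path, sep = "\t", quote = "", comment.char = "",
                    col.names = cols, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", rep("numeric", 10)))
  missing <- setdiff(unique(c(tab$query, tab$target)), names(length_lookup))
  if (length(missing) > 0L) {
    stop("id(s) absent from length_lookup: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  qlen <- unname(length_lookup[tab$query])
  slen <- unname(length_lookup[tab$target])
  qspan <- abs(tab$qend - tab$qstart) + 1
  sspan <- abs(tab$send - tab$sstart) + 1
  rank <- stats::ave(seq_len(nrow(tab)), tab$query, FUN = seq_along)
  data.frame(
    query = tab$query, target = tab$target,
    identity = tab$identity,
    query_coverage = 100 * qspan / qlen,
    target_coverage = 100 * sspan / slen,
    bitscore = tab$bitscore,
    rank = rank,
    self = tab$query == tab$target,
    stringsAsFactors = FALSE
  )
}
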