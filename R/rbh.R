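#' Reciprocal best hits between two species
#'
#' Implements the inter-species step of the modified RBH clustering: hits
#' are first filtered (identity and coverage strictly above 40% by default,
#' since the method keeps hits whose parameters *exceed* the threshold), then
#' each query's best surviving hit is taken (bit score, ties broken by higher
#' identity, then lexicographic target id), and an edge is emitted only when
#' two sequences are each other's best hit.
#'
#' @param hits_ab,hits_ba Hit `data.frame`s (see [read_blast_tab()]) for
#'   species A queried against B and B against A.
#' @param min_identity Percent identity threshold (strict, default 40).
#' @param min_coverage Percent coverage threshold (strict, default 40).
#' @param coverage Which coverage the filter applies to: `"both"` (default)
#'   or `"query"`.
#' @param species_of Optional named species lookup used to verify that the
#'   two tables really come from different species; same-species tables are
#'   an error (use [intra_species_better_pairs()] for those).
#' @return Edge `data.frame` with columns `a`, `b` (canonically ordered) and
#'   `class = "inter_species_rbh"`.
#' @export
reciprocal_best_pairs <- function(hits_ab, hits_ba, min_identity = 40,
                                  min_coverage = 40,
                                  coverage = c("both", "query"),
                                  species_of = NULL) {
  coverage <- match.arg(coverage)
  if (!is.null(species_of)) {
    sp_q <- unique(species_of[c(hits_ab$query, hits_ba$target)])
    sp_t <- unique(species_of[c(hits_ab$target, hits_ba$query)])
    if (length(intersect(sp_q, sp_t)) > 0L) {
      stop("hit tables appear to be from the same species; ",
           "use intra_species_better_pairs() for self-comparisons")
    }
  }
  best_ab <- best_hits(filter_hits(hits_ab, min_identity, min_coverage, coverage))
  best_ba <- best_hits(filter_hits(hits_ba, min_identity, min_coverage, coverage))
  if (length(best_ab) == 0L || length(best_ba) == 0L) return(empty_edges())
  a <- names(best_ab)
  b <- unname(best_ab)
  reciprocal <- !is.na(best_ba[b]) & best_ba[b] == a
  make_edges(a[reciprocal], b[reciprocal], "inter_species_rbh")
}

filter_hits <- function(hits, min_identity, min_coverage, coverage, strict = TRUE) {
  cmp <- if (strict) `>` else `>=`
  keep <- !hits$self & cmp(hits$identity, min_identity) &
    cmp(hits$query_coverage, min_coverage)
  if (coverage == "both") keep <- keep & cmp(hits$target_coverage, min_coverage)
  hits[keep, , drop = FALSE]
}

best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(setNames(character(0), character(0)))
  ord <- order(hits$query, -hits$bitscore, -hits$identity, hits$target)
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(hits$query)
  setNames(hits$target[first], hits$query[first])
}

make_edges <- function(a, b, class) {
  if (length(a) == 0L) return(empty_edges())
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  out <- unique(data.frame(a = lo, b = hi, class = class, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

empty_edges <- function() {
  data.frame(a = character(0), b = character(0), class = character(0),
             stringsAsFactors = FALSE)
}

#' Reciprocal better hits within one species
#'
#' The intra-species expansion step links recent paralogs: an edge (a, b) is
#' emitted when b lies within a's first `top_k` hits and a within b's first
#' `top_k` hits, with both hits at or above the 90% identity/coverage
#' thresholds. "First" follows the hit-list rank (file order for native
#' BLAST output); if ranks are absent the hits are ordered by bit score.
#'
#' @param self_hits Hit `data.frame` of one proteome compared against itself;
#'   self-hits (`query == target`) are ignored.
#' @param min_identity Percent identity threshold (inclusive, default 90).
#' @param min_coverage Percent coverage threshold (inclusive, default 90).
#' @param top_k Reciprocity window in the rank-ordered hit list (default 10).
#' @param coverage `"both"` (default) or `"query"`.
#' @return Edge `data.frame` with `class = "intra_species_better"`.
#' @export
intra_species_better_pairs <- function(self_hits, min_identity = 90,
                                       min_coverage = 90, top_k = 10,
                                       coverage = c("both", "query")) {
  coverage <- match.arg(coverage)
  hits <- self_hits
  if (is.null(hits$rank) || anyNA(hits$rank)) {
    ord <- order(hits$query, -hits$bitscore, hits$target)
    hits <- hits[ord, , drop = FALSE]
    hits$rank <- stats::ave(seq_len(nrow(hits)), hits$query, FUN = seq_along)
  }
  hits <- hits[!hits$self & hits$rank <= top_k, , drop = FALSE]
  hits <- filter_hits(transform(hits, self = FALSE), min_identity, min_coverage,
                      coverage, strict = FALSE)
  if (nrow(hits) == 0L) return(empty_edges())
  key <- paste(hits$query, hits$target, sep = "\r")
  rev_key <- paste(hits$target, hits$query, sep = "\r")
  mutual <- rev_key %in% key
  make_edges(hits$query[mutual], hits$target[mutual], "intra_species_better")
}

#' Merge homology edges into clusters by connected components
#'
#' Clusters are the connected components of the undirected edge graph over
#' `all_ids`; ids touched by no edge become singleton clusters. The result is
#' a partition and is independent of edge order.
#'
#' @param edges Edge `data.frame` with columns `a`, `b` (any extra columns
#'   are ignored), or NULL/empty for no edges.
#' @param all_ids Character vector of every protein id to be partitioned.
#' @return Named list of member-id character vectors; cluster names are
#'   `C<k>` numbered by first-member order in `all_ids`.
#' @export
merge_components <- function(edges, all_ids) {
  all_ids <- unique(as.character(all_ids))
  if (!is.null(edges) && nrow(edges) > 0L) {
    extra <- setdiff(unique(c(edges$a, edges$b)), all_ids)
    if (length(extra) > 0L) {
      stop("edge id(s) not in all_ids: ", paste(head(extra, 5L), collapse = ", "))
    }
    g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                       vertices = all_ids)
    memb <- igraph::components(g)$membership[all_ids]
  } else {
    memb <- setNames(seq_along(all_ids), all_ids)
  }
  # renumber components by first appearance so output order is deterministic
  first <- !duplicated(memb)
  renum <- setNames(seq_len(sum(first)), memb[first])
  memb <- renum[as.character(memb)]
  part <- split(all_ids, memb)
  names(part) <- sprintf("C%05d", as.integer(names(part)))
  part
}

#' Trim a cluster to members supported by a plastid-targeted anchor
#'
#' After merging, each cluster containing at least one plastid-predicted
#' member is trimmed: members are retained only if they are themselves
#' plastid-predicted or have a similarity hit at >= 40% identity and
#' coverage to at least one plastid member of the cluster. Pairs absent from
#' the hit table count as below threshold. Clusters with no plastid member
#' are returned unchanged with `no_plastid = TRUE`.
#'
#' @param members Character vector of cluster member ids.
#' @param hits Hit `data.frame` supplying pairwise identities/coverages.
#' @param plastid_set Character vector of plastid-predicted ids.
#' @param min_identity Percent identity threshold (inclusive, default 40).
#' @param min_coverage Percent coverage threshold (inclusive, default 40).
#' @param coverage `"both"` (default) or `"query"`.
#' @return List with `members` (retained ids), `removed`, and `no_plastid`.
#' @export
trim_cluster <- function(members, hits, plastid_set, min_identity = 40,
                         min_coverage = 40, coverage = c("both", "query")) {
  coverage <- match.arg(coverage)
  anchors <- intersect(members, plastid_set)
  if (length(anchors) == 0L) {
    return(list(members = members, removed = character(0), no_plastid = TRUE))
  }
  hits <- hits[hits$query %in% members & hits$target %in% members & !hits$self, ,
               drop = FALSE]
  ok <- hits$identity >= min_identity & hits$query_coverage >= min_coverage
  if (coverage == "both") ok <- ok & hits$target_coverage >= min_coverage
  hits <- hits[ok, , drop = FALSE]
  supported <- unique(c(hits$query[hits$target %in% anchors],
                        hits$target[hits$query %in% anchors]))
  keep <- members %in% c(anchors, supported)
  list(members = members[keep], removed = members[!keep], no_plastid = FALSE)
}

#' Run the full modified-RBH clustering pipeline
#'
#' Convenience wrapper chaining the four RBH stages on a combined hit table:
#' inter-species reciprocal best hits (40/40, strict) for every ordered
#' species pair, intra-species reciprocal better hits (90/90 within the top
#' 10), connected-component merging over all ids, and (when a plastid set is
#' given) plastid-anchored trimming.
#'
#' @param hits Combined hit `data.frame` covering all species pairs; species
#'   are taken from `species_of`.
#' @param all_ids Character vector of every protein id.
#' @param species_of Named species lookup for all ids.
#' @param plastid_set Optional plastid-predicted id set; enables trimming.
#' @param min_identity,min_coverage Inter-species thresholds (strict).
#' @param expand_identity,expand_coverage Intra-species thresholds (inclusive).
#' @param top_k Intra-species reciprocity window.
#' @return List with `partition` (possibly trimmed), `untrimmed`, and
#'   `edges`.
#' @export
rbh_cluster <- function(hits, all_ids, species_of, plastid_set = NULL,
                        min_identity = 40, min_coverage = 40,
                        expand_identity = 90, expand_coverage = 90, top_k = 10) {
  qsp <- unname(species_of[hits$query])
  tsp <- unname(species_of[hits$target])
  species <- sort(unique(c(qsp, tsp)))
  edges <- list()
  for (i in seq_along(species)) {
    for (j in seq_along(species)) {
      if (j <= i) next
      ab <- hits[qsp == species[i] & tsp == species[j], , drop = FALSE]
      ba <- hits[qsp == species[j] & tsp == species[i], , drop = FALSE]
      edges[[length(edges) + 1L]] <-
        reciprocal_best_pairs(ab, ba, min_identity, min_coverage)
    }
    self <- hits[qsp == species[i] & tsp == species[i], , drop = FALSE]
    edges[[length(edges) + 1L]] <-
      intra_species_better_pairs(self, expand_identity, expand_coverage, top_k)
  }
  edges <- do.call(rbind, edges)
  partition <- merge_components(edges, all_ids)
  out <- list(partition = partition, untrimmed = partition, edges = edges)
  if (!is.null(plastid_set)) {
    out$partition <- lapply(partition, function(m) {
      trim_cluster(m, hits, plastid_set)$members
    })
  }
  out
}
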