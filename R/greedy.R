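#' One greedy-centroid clustering pass
#'
#' Scans records in length-sorted order (longest first; ties broken by id
#' for determinism). Each record joins an existing centroid when its
#' alignment statistics against that centroid meet all thresholds —
#' the first qualifying centroid in founding order under `mode = "first"`
#' (the documented behaviour of UCLUST's Cluster_Fast), or the
#' best-identity qualifying centroid under `mode = "best"` — and otherwise
#' founds a new cluster with itself as centroid. Every member therefore
#' meets the thresholds against its centroid.
#'
#' Thresholds compare the incoming record as query and the centroid as
#' target: `identity` is matching columns over alignment columns,
#' `query_cov` the aligned fraction of the record, `target_cov` the aligned
#' fraction of the centroid. The initial 40% pass of the reference workflow
#' constrains identity and query coverage only; the 90% expansion passes
#' additionally constrain target coverage so that short sequences acting as
#' centroids cannot absorb much longer ones.
#'
#' @param records Protein-record `data.frame` (`id`, `sequence`, `length`).
#' @param identity Identity threshold in (0, 1].
#' @param query_cov Query-coverage threshold in \[0, 1\].
#' @param target_cov Target-coverage threshold in \[0, 1\] (0 disables it).
#' @param mode Candidate acceptance: `"first"` (default) or `"best"`.
#' @param presorted Set TRUE when `records` are already in the desired scan
#'   order (used by the reseeded expansion passes, where seeds are prepended
#'   ahead of the length-sorted list).
#' @param cache Optional alignment cache from `iterative_cluster()`; pass
#'   NULL for a standalone run.
#' @return Named list of member-id vectors; each cluster is named after its
#'   centroid (founding member, always the first element).
#' @export
greedy_pass <- function(records, identity = 0.4, query_cov = 0.4,
                        target_cov = 0, mode = c("first", "best"),
                        presorted = FALSE, cache = NULL) {
  mode <- match.arg(mode)
  stopifnot(identity > 0, identity <= 1)
  if (!presorted) {
    records <- records[order(-records$length, records$id), , drop = FALSE]
  }
  records <- records[!duplicated(records$id), , drop = FALSE]
  n <- nrow(records)
  centroids <- character(0)
  assignment <- setNames(rep(NA_character_, n), records$id)
  for (i in seq_len(n)) {
    id <- records$id[i]
    if (length(centroids) > 0L) {
      # one vectorised call: centroids as patterns, incoming record as subject
      st <- cached_align(records, centroids, id, cache)
      ok <- st$identity >= identity &
        st$target_coverage >= query_cov &      # coverage of the incoming record
        (target_cov <= 0 | st$query_coverage >= target_cov)  # of the centroid
      if (any(ok)) {
        hit <- if (mode == "first") which(ok)[1L] else which.max(ifelse(ok, st$identity, -1))
        assignment[id] <- centroids[hit]
        next
      }
    }
    centroids <- c(centroids, id)
    assignment[id] <- id
  }
  part <- split(names(assignment), assignment)[centroids]
  # centroid first, then members in scan order
  lapply(setNames(centroids, centroids), function(ctr) {
    mem <- part[[ctr]]
    c(ctr, setdiff(mem, ctr))
  })
}

#' Draw one random seed sequence per cluster
#'
#' The reseeding step of the iterative greedy clusterer: one member is drawn
#' uniformly at random from each cluster, and the chosen ids are returned in
#' length-sorted order (longest first, ties by id). Randomness comes from
#' R's global RNG, so a fixed `set.seed()` upstream makes the draw
#' reproducible; `iterative_cluster()` seeds all iterations from one seed.
#'
#' @param partition Named list of member-id vectors.
#' @param records Protein-record `data.frame` supplying lengths.
#' @return Character vector of seed ids, length-sorted.
#' @export
reseed <- function(partition, records) {
  stopifnot(length(partition) > 0L)
  seeds <- vapply(partition, function(m) m[sample.int(length(m), 1L)], character(1))
  lens <- setNames(records$length, records$id)[seeds]
  unname(seeds[order(-lens, seeds)])
}

#' Iterative greedy-centroid clustering with random reseeding
#'
#' The full modified greedy workflow: an initial length-sorted pass at
#' permissive thresholds (40% identity, 40% query coverage), followed by
#' `iterations` randomly reseeded passes at stringent identity (90%) with
#' both coverages at 40%. Each reseeded pass draws one random member per
#' initial cluster, prepends the length-sorted seeds to the length-sorted
#' full record list (duplicated ids are kept only at their seed position),
#' and re-clusters. Fragmented families are healed because near-identical
#' sequences that were split across initial clusters land in one cluster of
#' some reseeded run; clusters sharing any member across runs are merged by
#' connected components, so the merged cluster count is non-increasing in
#' the number of iterations. With `iterations = 0` the result equals the
#' initial pass.
#'
#' @param records Protein-record `data.frame`.
#' @param init_identity,init_qcov Initial-pass thresholds (fractions).
#' @param expand_identity Reseeded-pass identity threshold (fraction).
#' @param expand_cov Reseeded-pass query and target coverage threshold.
#' @param iterations Number of reseeded passes (the reference workflow used
#'   100; most clusters are fully expanded within about ten).
#' @param seed Optional integer seed governing all reseed draws.
#' @param mode Candidate acceptance mode, see [greedy_pass()].
#' @return List with `partition` (merged), `initial` (initial-pass
#'   partition), `runs` (the per-iteration partitions), and `counts` (merged
#'   cluster count after the initial pass and after each iteration).
#' @export
iterative_cluster <- function(records, init_identity = 0.4, init_qcov = 0.4,
                              expand_identity = 0.9, expand_cov = 0.4,
                              iterations = 100, seed = NULL,
                              mode = c("first", "best")) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  records <- records[order(-records$length, records$id), , drop = FALSE]
  cache <- new_alignment_cache()
  initial <- greedy_pass(records, init_identity, init_qcov, target_cov = 0,
                         mode = mode, presorted = TRUE, cache = cache)
  co_edges <- partition_edges(initial)
  counts <- integer(iterations + 1L)
  counts[1L] <- length(initial)
  runs <- list()
  for (it in seq_len(iterations)) {
    seeds <- reseed(initial, records)
    scan <- rbind(records[match(seeds, records$id), , drop = FALSE], records)
    scan <- scan[!duplicated(scan$id), , drop = FALSE]
    run <- greedy_pass(scan, expand_identity, expand_cov,
                       target_cov = expand_cov, mode = mode,
                       presorted = TRUE, cache = cache)
    runs[[it]] <- run
    co_edges <- rbind(co_edges, partition_edges(run))
    counts[it + 1L] <- length(merge_components(co_edges, records$id))
  }
  list(partition = merge_components(co_edges, records$id),
       initial = initial, runs = runs, counts = counts)
}

# Chain edges linking all members of each cluster (enough for connectivity).
partition_edges <- function(partition) {
  multi <- partition[lengths(partition) > 1L]
  if (length(multi) == 0L) return(empty_edges())
  do.call(rbind, lapply(multi, function(m) {
    make_edges(m[-length(m)], m[-1L], "co_member")
  }))
}
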