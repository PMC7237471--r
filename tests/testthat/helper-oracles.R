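# Independent brute-force reference implementations. These re-derive each
# result directly from its definition (plain loops, no shared code with the
# package's algorithms) and are used to cross-check the implementations on
# randomized small instances.

oracle_union_find <- function(edges, ids) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (!is.null(edges) && nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges$a[k])
      rb <- find(edges$b[k])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(ids, find, character(1))
  unname(split(ids, roots))
}

# Canonical representation of a partition for set equality.
partition_key <- function(part) {
  unname(sort(vapply(part, function(m) paste(sort(m), collapse = "|"),
                     character(1))))
}

edge_key <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) return(character(0))
  sort(paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b)))
}

oracle_rbh_edges <- function(hits_ab, hits_ba, min_id = 40, min_cov = 40) {
  survives <- function(h) {
    h[!h$self & h$identity > min_id & h$query_coverage > min_cov &
        h$target_coverage > min_cov, , drop = FALSE]
  }
  best_of <- function(h, q) {
    rows <- h[h$query == q, , drop = FALSE]
    if (nrow(rows) == 0L) return(NA_character_)
    rows <- rows[order(-rows$bitscore, -rows$identity, rows$target), , drop = FALSE]
    rows$target[1L]
  }
  ab <- survives(hits_ab)
  ba <- survives(hits_ba)
  out <- list()
  for (q in unique(ab$query)) {
    b <- best_of(ab, q)
    if (is.na(b)) next
    if (identical(best_of(ba, b), q)) out[[length(out) + 1L]] <- sort(c(q, b))
  }
  if (length(out) == 0L) return(data.frame(a = character(0), b = character(0)))
  unique(data.frame(a = vapply(out, `[`, "", 1L), b = vapply(out, `[`, "", 2L),
                    stringsAsFactors = FALSE))
}

oracle_intra_edges <- function(self_hits, min_id = 90, min_cov = 90, top_k = 10) {
  h <- self_hits[!self_hits$self, , drop = FALSE]
  qualifies <- function(a, b) {
    rows <- h[h$query == a & h$target == b, , drop = FALSE]
    any(rows$rank <= top_k & rows$identity >= min_id &
          rows$query_coverage >= min_cov & rows$target_coverage >= min_cov)
  }
  ids <- unique(c(h$query, h$target))
  out <- list()
  for (a in ids) for (b in ids) {
    if (a < b && qualifies(a, b) && qualifies(b, a)) {
      out[[length(out) + 1L]] <- c(a, b)
    }
  }
  if (length(out) == 0L) return(data.frame(a = character(0), b = character(0)))
  data.frame(a = vapply(out, `[`, "", 1L), b = vapply(out, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

oracle_trim <- function(members, hits, plastid_set, min_id = 40, min_cov = 40) {
  anchors <- intersect(members, plastid_set)
  keep <- character(0)
  for (m in members) {
    if (m %in% anchors) {
      keep <- c(keep, m)
      next
    }
    ok <- FALSE
    for (a in anchors) {
      rows <- hits[((hits$query == m & hits$target == a) |
                      (hits$query == a & hits$target == m)) & !hits$self, ,
                   drop = FALSE]
      if (any(rows$identity >= min_id & rows$query_coverage >= min_cov &
                rows$target_coverage >= min_cov)) {
        ok <- TRUE
        break
      }
    }
    if (ok) keep <- c(keep, m)
  }
  keep
}

oracle_vote <- function(calls, predictors, m) {
  out <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    votes <- 0L
    for (p in predictors) if (isTRUE(calls[i, p])) votes <- votes + 1L
    out[i] <- votes >= m
  }
  setNames(out, rownames(calls))
}

# Literal restatement of the conservation category rules.
oracle_classify <- function(profile, tax, params = classification_params()) {
  if (nrow(profile) == 1L) return("discarded_single_species")
  sp <- profile$species
  plastid_sp <- sp[profile$n_plastid > 0]
  ok <- TRUE
  for (i in seq_len(nrow(profile))) {
    if (profile$n_plastid[i] == 0 && profile$n_other[i] < params$fn_exemption) {
      ok <- FALSE
    }
  }
  if (nrow(profile) >= params$min_species_conserved && ok &&
      length(plastid_sp) > 0L) {
    return("conserved")
  }
  lin <- tax$species
  og_clade <- lin$clade[lin$species == tax$outgroup]
  if (length(plastid_sp) > 0L) {
    for (level in c("family", "subclade", "clade")) {
      labels <- unique(lin[[level]][match(plastid_sp, lin$species)])
      if (length(labels) != 1L) next
      inside <- lin$species[lin[[level]] == labels]
      outside <- setdiff(sp, inside)
      bad_outside <- FALSE
      for (o in outside) {
        row <- profile[profile$species == o, ]
        if (row$n_plastid > 0 || row$n_other >= params$fn_exemption) bad_outside <- TRUE
      }
      enough <- if (length(inside) == 1L) {
        inside == tax$outgroup &&
          sum(profile$n_plastid[sp %in% inside]) >= params$outgroup_min_plastid
      } else {
        length(plastid_sp) >= params$min_clade_species
      }
      if (enough && !bad_outside) return("semi_conserved")
    }
  }
  if (nrow(profile) >= params$min_species_nptp && length(plastid_sp) == 1L) {
    return("nptp")
  }
  "unclassified"
}

oracle_mean_jaccard <- function(members, annotations) {
  sets <- list()
  for (m in members) {
    if (m %in% names(annotations) && length(annotations[[m]]) > 0L) {
      sets[[length(sets) + 1L]] <- annotations[[m]]
    }
  }
  if (length(sets) < 2L) return(NA_real_)
  vals <- c()
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i < j) {
      vals <- c(vals, length(intersect(sets[[i]], sets[[j]])) /
                  length(union(sets[[i]], sets[[j]])))
    }
  }
  mean(vals)
}

# Brute-force greedy scan (no cache, no vectorisation): same alignment
# primitive, independent clustering logic.
oracle_greedy <- function(records, id_thr, qcov_thr, tcov_thr, mode = "first") {
  records <- records[order(-records$length, records$id), , drop = FALSE]
  centroids <- character(0)
  assign_to <- setNames(character(nrow(records)), records$id)
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    best <- NA_character_
    best_ident <- -1
    for (ctr in centroids) {
      st <- pairwise_identity(records$sequence[records$id == id],
                              records$sequence[records$id == ctr])
      qual <- st$identity >= id_thr && st$query_coverage >= qcov_thr &&
        (tcov_thr <= 0 || st$target_coverage >= tcov_thr)
      if (qual) {
        if (mode == "first") {
          best <- ctr
          break
        } else if (st$identity > best_ident) {
          best <- ctr
          best_ident <- st$identity
        }
      }
    }
    if (is.na(best)) {
      centroids <- c(centroids, id)
      assign_to[id] <- id
    } else {
      assign_to[id] <- best
    }
  }
  split(names(assign_to), assign_to)
}
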