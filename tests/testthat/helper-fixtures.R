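# Fixture builders. Everything is generated in code at test time; files go
# to tempdir().

# Random similarity-hit table between two id sets (or within one when
# ids_b is NULL), with self-consistent ranks.
rand_hit_table <- function(ids_a, ids_b = NULL, p_hit = 0.6) {
  intra <- is.null(ids_b)
  targets <- if (intra) ids_a else ids_b
  rows <- list()
  for (q in ids_a) {
    for (t in targets) {
      if (runif(1) > p_hit) next
      rows[[length(rows) + 1L]] <- data.frame(
        query = q, target = t,
        identity = runif(1, 10, 100),
        query_coverage = runif(1, 10, 100),
        target_coverage = runif(1, 10, 100),
        bitscore = round(runif(1, 30, 900), 1),
        self = q == t, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(query = character(0), target = character(0),
                      identity = numeric(0), query_coverage = numeric(0),
                      target_coverage = numeric(0), bitscore = numeric(0),
                      rank = integer(0), self = logical(0)))
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$query, -hits$bitscore, hits$target), , drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$query, FUN = seq_along)
  rownames(hits) <- NULL
  hits
}

# Random per-species plastid/non-plastid count profile over the default
# 15-species taxonomy.
rand_profile <- function(tax, max_species = 15) {
  n <- sample.int(max_species, 1L)
  sp <- sample(tax$species$species, n)
  data.frame(species = sp,
             n_plastid = rpois(n, 0.8),
             n_other = rpois(n, 2),
             stringsAsFactors = FALSE)
}

# Family corpus sized for alignment-based clustering tests.
small_cluster_corpus <- function(n_families = 6, n_species = 4, seed = 7,
                                 paralog_mean = 0.5) {
  tax <- default_taxonomy()
  keep <- c("Atr", head(setdiff(tax$species$species, "Atr"), n_species - 1L))
  tax_small <- taxonomy(tax$species[tax$species$species %in% keep, ], "Atr")
  simulate_corpus(n_families = n_families, tax = tax_small,
                  within_identity = 0.8, paralog_mean = paralog_mean,
                  length_range = c(120, 250), seed = seed)
}

truth_partition <- function(corpus) {
  unname(split(corpus$truth$id, corpus$truth$family))
}

# A family that the initial greedy pass provably splits and reseeding heals:
# A is a full-length protein, B a chimera whose tail is homologous to A
# (75% identity over 240 residues) behind 150 unrelated residues, and C the
# unrelated 160-residue prefix of B. The initial 40% pass clusters {A, B}
# (B's tail aligns to A) but C has no homology to A and founds its own
# cluster; any 90% reseeded pass re-links C to B (exact prefix), merging
# the family.
fragmentation_records <- function(seed = 77) {
  set.seed(seed)
  core <- random_protein(400)
  b_tail <- mutate_to_identity(substr(core, 1, 240), 0.75)
  junk <- substr(random_protein(151), 2, 151)
  B <- paste0(junk, b_tail)
  C <- substr(B, 1, 160)
  data.frame(id = c("A", "B", "C"), sequence = c(core, B, C),
             length = nchar(c(core, B, C)), stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

targetp_fixture <- function() {
  write_lines_tmp(c(
    "### targetp v1.1 prediction results ##################################",
    "Name                  Len            cTP   mTP    SP  other  Loc  RC",
    "----------------------------------------------------------------------",
    "AT1G01010.1           429          0.814 0.102 0.033  0.050   C    2",
    "AT1G01020.1           245          0.120 0.802 0.031  0.110   M    3",
    "AT1G01030.1           358          0.055 0.043 0.869  0.033   S    1",
    "AT1G01040.1           196          0.200 0.180 0.150  0.470   _    4",
    "----------------------------------------------------------------------"
  ))
}

localizer_fixture <- function() {
  write_lines_tmp(c(
    "# LOCALIZER 1.0.2 Results",
    "Identifier\tChloroplast\tMitochondria\tNucleus",
    "-----------\t-----------\t-----------\t-------",
    "AT1G01010.1\tY (0.916)\t-\t-",
    "AT1G01020.1\t-\tY (0.877)\t-",
    "AT1G01030.1\t-\t-\tY",
    "AT1G01040.1\tY (0.555)\t-\tY"
  ))
}

generic_calls_fixture <- function() {
  prot <- sprintf("P%02d", 1:5)
  lines <- c("protein\tpredictor\tcall",
             paste(rep(prot, 2),
                   rep(c("MultiLoc2", "PCLR"), each = 5),
                   rep(c("plastid", "other", "plastid", "other", "plastid"), 2),
                   sep = "\t"))
  write_lines_tmp(lines, ".tsv")
}

# outfmt-6 line builder
blast6_line <- function(q, s, pid, qstart, qend, sstart, send, bits,
                        evalue = "1e-50") {
  paste(q, s, pid, abs(qend - qstart) + 1, 5, 1, qstart, qend, sstart, send,
        evalue, bits, sep = "\t")
}
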