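# Synthetic-data generators. They emulate the statistical structure the
# pipeline assumes -- homologous families with controlled identity and
# paralogy, per-species targeting truth, predictor calls at chosen error
# rates, and hit tables consistent with the family structure -- so that every
# stage is testable without external proteomes or predictor binaries.
# Transit peptides exist only as truth flags, not sequence motifs: the
# pipeline consumes predictor calls, never raw cTP sequence.

#' Random protein sequence
#'
#' Uniform over the 20 standard residues, always starting with methionine.
#'
#' @param length Residue count (>= 1).
#' @return Character scalar.
#' @export
random_protein <- function(length) {
  stopifnot(length >= 1)
  aa <- setdiff(aa_letters(), "X")
  paste(c("M", sample(aa, length - 1L, replace = TRUE)), collapse = "")
}

#' Mutate a sequence to a target identity
#'
#' Substitutes `round((1 - identity) * length)` uniformly chosen positions
#' (never position 1, preserving the start methionine) with a different
#' residue, so the realised Hamming identity to the input is within one
#' substitution of the target. Length is preserved; no indels are
#' introduced.
#'
#' @param seq Amino-acid sequence.
#' @param identity Target identity in (0, 1].
#' @return Mutated sequence.
#' @export
mutate_to_identity <- function(seq, identity) {
  if (is.na(identity) || identity <= 0 || identity > 1) {
    stop("identity must be in (0, 1]")
  }
  n <- nchar(seq)
  k <- min(round_half_up((1 - identity) * n), n - 1L)
  if (k == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- 1L + sample.int(n - 1L, k)
  aa <- setdiff(aa_letters(), "X")
  repl <- sample(aa, k, replace = TRUE)
  clash <- repl == chars[pos]
  while (any(clash)) {
    repl[clash] <- sample(aa, sum(clash), replace = TRUE)
    clash <- repl == chars[pos]
  }
  chars[pos] <- repl
  paste(chars, collapse = "")
}

#' Simulate a corpus of homologous protein families with targeting truth
#'
#' Each family descends from an ancestral sequence (length uniform on
#' `length_range`, starting with methionine). Every present species receives
#' one ortholog, mutated to `within_identity` of the ancestor, plus a
#' Poisson(`paralog_mean`) number of paralogs derived from the species
#' ortholog at `paralog_identity`. Targeting truth follows the family's
#' scenario: `conserved` families are plastid-targeted in every species,
#' `clade_specific` only within one clade (drawn from the non-outgroup
#' clades), `species_unique` in a single random species, and `non_plastid`
#' nowhere.
#'
#' Paralog intensity is scenario-dependent by default, reflecting the
#' family-size structure observed in real angiosperm proteomes: conserved
#' plastid-targeted families are large (on the order of a hundred sequences
#' across fifteen species, i.e. several copies per species — the very
#' regime in which the four-non-plastid false-negative exemption of the
#' conservation classifier is meaningful), whereas multi-species families
#' with clade- or species-restricted targeting are typically small ortholog
#' sets. The default is therefore `paralog_mean = 6` extra copies per
#' species for `conserved` families and `0` for the other scenarios; a
#' scalar applies one intensity to every scenario.
#'
#' @param n_families Number of families.
#' @param tax A `taxonomy` object (default the built-in 15 species).
#' @param scenario_mix Named fractions over
#'   `conserved`/`clade_specific`/`species_unique`/`non_plastid`; must sum
#'   to 1.
#' @param within_identity Ortholog identity to the family ancestor; pairwise
#'   within-family identity is roughly its square.
#' @param paralog_mean Poisson mean of extra per-species copies: a scalar,
#'   or a named vector keyed by scenario.
#' @param paralog_identity Identity of a paralog to its species ortholog.
#' @param presence_prob Probability each non-anchor species is present.
#' @param length_range Ancestral length range (uniform).
#' @param seed Optional integer seed (bit-reproducible output).
#' @return List with `records` (protein-record `data.frame` over all
#'   species), `truth` (`data.frame`: id, family, species, plastid),
#'   and `families` (`data.frame`: family, scenario, group, length,
#'   n_species).
#' @export
simulate_corpus <- function(n_families = 20,
                            tax = default_taxonomy(),
                            scenario_mix = c(conserved = 0.25,
                                             clade_specific = 0.25,
                                             species_unique = 0.25,
                                             non_plastid = 0.25),
                            within_identity = 0.85,
                            paralog_mean = c(conserved = 6, clade_specific = 0,
                                             species_unique = 0, non_plastid = 0),
                            paralog_identity = 0.97,
                            presence_prob = 1,
                            length_range = c(150, 800),
                            seed = NULL) {
  if (abs(sum(scenario_mix) - 1) > 1e-8) stop("scenario_mix must sum to 1")
  known <- c("conserved", "clade_specific", "species_unique", "non_plastid")
  if (!all(names(scenario_mix) %in% known)) {
    stop("unknown scenario(s): ",
         paste(setdiff(names(scenario_mix), known), collapse = ", "))
  }
  if (is.null(names(paralog_mean))) {
    paralog_mean <- setNames(rep(paralog_mean[[1L]], length(known)), known)
  } else if (!all(known %in% names(paralog_mean))) {
    stop("per-scenario paralog_mean must name every scenario")
  }
  if (!is.null(seed)) set.seed(seed)
  species <- tax$species$species
  clades <- setdiff(unique(tax$species$clade), lineage_of(tax, tax$outgroup, "clade"))
  scen <- sample(names(scenario_mix), n_families, replace = TRUE,
                 prob = scenario_mix)
  rec <- list(); tru <- list(); fam <- list()
  for (f in seq_len(n_families)) {
    fid <- sprintf("F%03d", f)
    len <- sample(length_range[1L]:length_range[2L], 1L)
    anc <- random_protein(len)
    present <- species[runif(length(species)) <= presence_prob]
    if (length(present) == 0L) present <- sample(species, 1L)
    group <- switch(scen[f],
      clade_specific = sample(clades, 1L),
      species_unique = sample(present, 1L),
      NA_character_)
    plastid_species <- switch(scen[f],
      conserved = present,
      clade_specific = intersect(present, species_in(tax, group)),
      species_unique = group,
      non_plastid = character(0))
    for (s in present) {
      ortho <- mutate_to_identity(anc, within_identity)
      n_para <- rpois(1L, paralog_mean[[scen[f]]])
      seqs <- c(ortho, vapply(seq_len(n_para), function(i) {
        mutate_to_identity(ortho, paralog_identity)
      }, character(1)))
      ids <- sprintf("%s_%s_%02d", s, fid, seq_along(seqs))
      rec[[length(rec) + 1L]] <- data.frame(
        id = ids, species = s, sequence = seqs, length = nchar(seqs),
        stringsAsFactors = FALSE)
      tru[[length(tru) + 1L]] <- data.frame(
        id = ids, family = fid, species = s,
        plastid = s %in% plastid_species, stringsAsFactors = FALSE)
    }
    fam[[length(fam) + 1L]] <- data.frame(
      family = fid, scenario = scen[f], group = group, length = len,
      n_species = length(present), stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, rec), truth = do.call(rbind, tru),
       families = do.call(rbind, fam))
}

#' Simulate predictor calls at known sensitivity and false-positive rate
#'
#' Independent Bernoulli calls: a truly plastid-targeted protein is called
#' plastid with probability `se`, a non-plastid protein with probability
#' `fpr`; predictors are mutually independent given the truth.
#'
#' @param truth Truth `data.frame` (columns `id`, `plastid`) from
#'   [simulate_corpus()], or any data.frame with those columns.
#' @param predictors `data.frame` with columns `name`, `se`, `fpr`.
#' @param seed Optional integer seed.
#' @return A `call_table` logical matrix (proteins x predictors).
#' @export
simulate_calls <- function(truth, predictors, seed = NULL) {
  stopifnot(all(c("name", "se", "fpr") %in% names(predictors)))
  if (any(predictors$se < 0 | predictors$se > 1 |
            predictors$fpr < 0 | predictors$fpr > 1)) {
    stop("se and fpr must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  m <- vapply(seq_len(nrow(predictors)), function(j) {
    p <- ifelse(truth$plastid, predictors$se[j], predictors$fpr[j])
    rbinom(n, 1L, p) == 1L
  }, logical(n))
  dimnames(m) <- list(truth$id, predictors$name)
  class(m) <- c("call_table", class(m))
  m
}

#' Simulate an all-vs-all similarity hit table for a corpus
#'
#' Emits one hit per ordered within-family sequence pair (plus self-hits,
#' marked as such) with identity equal to the realised Hamming identity of
#' the pair (optionally jittered), full coverage, and a bit score monotone
#' in identity times length; ranks within each query follow descending bit
#' score. Optional spurious cross-family hits are added at a low identity to
#' exercise the clustering filters.
#'
#' @param corpus Corpus list from [simulate_corpus()].
#' @param identity_noise Standard deviation (percent) of Gaussian jitter
#'   added to hit identities (default 0).
#' @param spurious_rate Expected number of spurious cross-family hits per
#'   sequence (default 0).
#' @param spurious_identity Identity (percent) assigned to spurious hits.
#' @param seed Optional integer seed.
#' @return Hit `data.frame` in the [read_blast_tab()] layout.
#' @export
simulate_hit_table <- function(corpus, identity_noise = 0, spurious_rate = 0,
                               spurious_identity = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rec <- corpus$records
  fam <- setNames(corpus$truth$family, corpus$truth$id)[rec$id]
  rows <- lapply(split(seq_len(nrow(rec)), fam), function(idx) {
    ids <- rec$id[idx]
    seqs <- rec$sequence[idx]
    lens <- rec$length[idx]
    n <- length(ids)
    pairs <- expand.grid(q = seq_len(n), t = seq_len(n))
    ident <- vapply(seq_len(nrow(pairs)), function(k) {
      q <- pairs$q[k]; t <- pairs$t[k]
      if (q == t) return(100)
      100 * hamming_identity(seqs[q], seqs[t])
    }, numeric(1))
    data.frame(query = ids[pairs$q], target = ids[pairs$t],
               identity = ident,
               query_coverage = 100, target_coverage = 100,
               length = lens[pairs$q],
               self = pairs$q == pairs$t, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  if (identity_noise > 0) {
    jitter <- stats::rnorm(nrow(hits), 0, identity_noise)
    hits$identity <- pmin(pmax(hits$identity + ifelse(hits$self, 0, jitter), 0), 100)
  }
  if (spurious_rate > 0) {
    n_spur <- rpois(1L, spurious_rate * nrow(rec))
    if (n_spur > 0L) {
      q <- sample.int(nrow(rec), n_spur, replace = TRUE)
      t <- sample.int(nrow(rec), n_spur, replace = TRUE)
      cross <- fam[q] != fam[t]
      if (any(cross)) {
        hits <- rbind(hits, data.frame(
          query = rec$id[q[cross]], target = rec$id[t[cross]],
          identity = spurious_identity,
          query_coverage = 100, target_coverage = 100,
          length = rec$length[q[cross]], self = FALSE,
          stringsAsFactors = FALSE))
      }
    }
  }
  hits$bitscore <- 2 * (hits$identity / 100) * hits$length
  hits$length <- NULL
  ord <- order(hits$query, -hits$bitscore, hits$target)
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$query, FUN = seq_along)
  rownames(hits) <- NULL
  hits
}

# Hamming identity over the shorter common span of two sequences.
hamming_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  sum(av == bv) / max(nchar(a), nchar(b))
}
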