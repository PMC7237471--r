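#' Filter a predicted proteome before targeting prediction
#'
#' Whole-proteome preprocessing: sequences shorter than 100 residues or not
#' beginning with methionine are removed, since they are usually gene-model
#' fragments or mis-annotated starts for which transit-peptide prediction is
#' meaningless.
#'
#' @param records Protein-record `data.frame`.
#' @param min_length Minimum residue count (default 100, inclusive).
#' @return The retained records, with a `removal_report` attribute counting
#'   removals by reason (`too_short`, `no_start_met`, `both`).
#' @export
preprocess_proteome <- function(records, min_length = 100) {
  short <- records$length < min_length
  no_met <- substr(records$sequence, 1L, 1L) != "M"
  keep <- !short & !no_met
  out <- records[keep, , drop = FALSE]
  attr(out, "removal_report") <- c(
    too_short = sum(short & !no_met),
    no_start_met = sum(no_met & !short),
    both = sum(short & no_met),
    kept = sum(keep)
  )
  out
}

#' 2-of-2 TargetP + Localizer consensus targeting call
#'
#' The genome-scale consensus rule: a protein is classified plastid-targeted
#' only when both TargetP and Localizer predict a chloroplast transit
#' peptide; "1 of 2" and "0 of 2" predictions are non-plastid. Equivalent to
#' `apply_workflow(c("TargetP", "Localizer"), 2, calls)`.
#'
#' @param calls A `call_table` containing TargetP and Localizer columns.
#' @param predictors The two consensus predictor columns.
#' @return Named logical vector of plastid flags.
#' @export
consensus_targeting <- function(calls, predictors = c("TargetP", "Localizer")) {
  apply_workflow(predictors, length(predictors), calls)
}

#' Classification parameters for cluster conservation categories
#'
#' @param min_species_conserved Minimum species in a cluster for the
#'   conserved category (default 13 of 15).
#' @param fn_exemption Number of non-plastid-predicted sequences that lets a
#'   species count as "likely plastid" despite having no positive call — a
#'   correction for the roughly 39% false-negative rate of the consensus
#'   predictor (default 4).
#' @param min_clade_species Minimum species with plastid members inside a
#'   clade for the semi-conserved category (default 2).
#' @param min_species_nptp Minimum species present for the NPTP category
#'   (default 3).
#' @param outgroup_min_plastid Minimum plastid-predicted sequences for
#'   outgroup-specific (single-species clade) semi-conservation (default 2).
#' @return List of class `classification_params`.
#' @export
classification_params <- function(min_species_conserved = 13, fn_exemption = 4,
                                  min_clade_species = 2, min_species_nptp = 3,
                                  outgroup_min_plastid = 2) {
  stopifnot(min_species_conserved >= 1, fn_exemption >= 1,
            min_clade_species >= 1, min_species_nptp >= 1)
  structure(list(min_species_conserved = min_species_conserved,
                 fn_exemption = fn_exemption,
                 min_clade_species = min_clade_species,
                 min_species_nptp = min_species_nptp,
                 outgroup_min_plastid = outgroup_min_plastid),
            class = "classification_params")
}

#' Per-species plastid profile of a cluster
#'
#' @param members Character vector of cluster member ids.
#' @param species_of Named species lookup covering all members.
#' @param plastid_set Character vector of plastid-predicted ids.
#' @return `data.frame` with columns `species`, `n_plastid`, `n_other`.
#' @export
build_profile <- function(members, species_of, plastid_set) {
  sp <- species_of[members]
  if (anyNA(sp)) {
    stop("species unknown for member(s): ",
         paste(head(members[is.na(sp)], 5L), collapse = ", "))
  }
  plastid <- members %in% plastid_set
  species <- unique(unname(sp))
  data.frame(
    species = species,
    n_plastid = vapply(species, function(s) sum(plastid[sp == s]), integer(1)),
    n_other = vapply(species, function(s) sum(!plastid[sp == s]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Classify one cluster into a conservation category
#'
#' Applies the category rules in order:
#'
#' 1. Clusters with members from a single species (including singletons) are
#'    `discarded_single_species` — likely annotation artifacts.
#' 2. `conserved`: at least `min_species_conserved` species present, at
#'    least one of them with a plastid-predicted member, and *every* present
#'    species either has a plastid member or carries at least `fn_exemption`
#'    non-plastid members (the false-negative exemption).
#' 3. `semi_conserved`: plastid targeting confined to one taxonomic group —
#'    the smallest lineage level (family, then subclade, then clade) in which
#'    at least `min_clade_species` species have plastid members, provided no
#'    species outside the group has a plastid member or reaches the
#'    `fn_exemption` count. The outgroup clade, being a single species,
#'    instead requires `outgroup_min_plastid` plastid sequences.
#' 4. `nptp`: at least `min_species_nptp` species present and exactly one
#'    species with plastid members — a candidate recent transit-peptide gain.
#' 5. Otherwise `unclassified`.
#'
#' @param profile Species profile from [build_profile()].
#' @param tax A `taxonomy` object covering the profile's species.
#' @param params A [classification_params()] list.
#' @return List with `category` and, where applicable, `group` (the
#'   qualifying lineage label for `semi_conserved`, the single plastid
#'   species for `nptp`).
#' @export
classify_cluster <- function(profile, tax, params = classification_params()) {
  stopifnot(nrow(profile) > 0L)
  if (nrow(profile) == 1L) {
    return(list(category = "discarded_single_species", group = NA_character_))
  }
  plastid_sp <- profile$species[profile$n_plastid > 0L]
  qualifies <- profile$n_plastid > 0L | profile$n_other >= params$fn_exemption
  if (nrow(profile) >= params$min_species_conserved &&
      length(plastid_sp) > 0L && all(qualifies)) {
    return(list(category = "conserved", group = NA_character_))
  }
  if (length(plastid_sp) > 0L) {
    for (level in c("family", "subclade", "clade")) {
      labels <- unique(lineage_of(tax, plastid_sp, level))
      if (length(labels) != 1L) next
      group <- labels
      inside <- species_in(tax, group)
      outgroup_clade <- lineage_of(tax, tax$outgroup, "clade")
      single_species_group <- length(inside) == 1L
      enough_inside <- if (single_species_group) {
        group %in% c(outgroup_clade,
                     lineage_of(tax, tax$outgroup, "subclade"),
                     lineage_of(tax, tax$outgroup, "family")) &&
          sum(profile$n_plastid[profile$species %in% inside]) >= params$outgroup_min_plastid
      } else {
        length(plastid_sp) >= params$min_clade_species
      }
      outside <- profile[!profile$species %in% inside, , drop = FALSE]
      outside_clean <- all(outside$n_plastid == 0L) &&
        all(outside$n_other < params$fn_exemption)
      if (enough_inside && outside_clean) {
        return(list(category = "semi_conserved", group = group))
      }
    }
  }
  if (nrow(profile) >= params$min_species_nptp && length(plastid_sp) == 1L) {
    return(list(category = "nptp", group = plastid_sp))
  }
  list(category = "unclassified", group = NA_character_)
}

#' Classify every cluster and summarise per species
#'
#' Runs [build_profile()] and [classify_cluster()] over a partition and
#' produces both the per-cluster classification table and the per-species
#' census used for cross-species comparison: total clusters containing the
#' species, clusters with a plastid member of that species, clusters in
#' which that species is the only one with plastid members, single-species
#' clusters, and NPTP counts.
#'
#' @param partition Named list of member-id vectors.
#' @param plastid_set Character vector of plastid-predicted ids (e.g. from
#'   [consensus_targeting()]).
#' @param species_of Named species lookup.
#' @param tax A `taxonomy` object.
#' @param params A [classification_params()] list.
#' @return List with `classification` (`data.frame`: cluster, category,
#'   group, n_species, n_members, n_plastid) and `by_species`
#'   (`data.frame`: species, total_clusters, plastid_clusters,
#'   unique_plastid, single_species_clusters, nptp).
#' @export
classify_all <- function(partition, plastid_set, species_of, tax,
                         params = classification_params()) {
  if (length(partition) == 0L) {
    return(list(
      classification = data.frame(cluster = character(0), category = character(0),
                                  group = character(0), n_species = integer(0),
                                  n_members = integer(0), n_plastid = integer(0)),
      by_species = data.frame(species = character(0))
    ))
  }
  profiles <- lapply(partition, build_profile, species_of = species_of,
                     plastid_set = plastid_set)
  cls <- lapply(profiles, classify_cluster, tax = tax, params = params)
  classification <- data.frame(
    cluster = names(partition),
    category = vapply(cls, `[[`, character(1), "category"),
    group = vapply(cls, `[[`, character(1), "group"),
    n_species = vapply(profiles, nrow, integer(1)),
    n_members = vapply(partition, length, integer(1)),
    n_plastid = vapply(profiles, function(p) sum(p$n_plastid), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  species <- tax$species$species
  by_species <- do.call(rbind, lapply(species, function(s) {
    has_sp <- vapply(profiles, function(p) s %in% p$species, logical(1))
    sp_plastid <- vapply(profiles, function(p) {
      s %in% p$species && p$n_plastid[p$species == s] > 0L
    }, logical(1))
    only_plastid <- vapply(profiles, function(p) {
      plastid_sp <- p$species[p$n_plastid > 0L]
      length(plastid_sp) == 1L && plastid_sp == s
    }, logical(1))
    data.frame(
      species = s,
      total_clusters = sum(has_sp),
      plastid_clusters = sum(sp_plastid),
      unique_plastid = sum(only_plastid),
      single_species_clusters = sum(has_sp & classification$n_species == 1L),
      nptp = sum(classification$category == "nptp" & classification$group == s,
                 na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  list(classification = classification, by_species = by_species)
}
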