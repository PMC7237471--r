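#' Census of a cluster partition
#'
#' Summarises a partition the way comparative clustering studies report it:
#' total clusters, singletons, single-species clusters (both typically
#' discarded as annotation artifacts), the histogram of clusters by number
#' of species represented (the distribution that is bimodal in real
#' angiosperm data), and per-species cluster totals.
#'
#' @param partition Named list of member-id vectors.
#' @param species_of Named species lookup covering all members.
#' @return List of class `cluster_census`: `total`, `n_singleton`,
#'   `n_single_species`, `single_species_fraction` (percent),
#'   `by_species_count` (named integer vector over 1..max species), and
#'   `per_species` (`data.frame`: species, n_clusters).
#' @export
cluster_census <- function(partition, species_of) {
  n_species <- vapply(partition, function(m) {
    length(unique(unname(species_of[m])))
  }, integer(1))
  sizes <- lengths(partition)
  hist <- table(factor(n_species, levels = seq_len(max(n_species, 1L))))
  species <- sort(unique(unname(species_of[unlist(partition, use.names = FALSE)])))
  per_species <- data.frame(
    species = species,
    n_clusters = vapply(species, function(s) {
      sum(vapply(partition, function(m) s %in% species_of[m], logical(1)))
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    total = length(partition),
    n_singleton = sum(sizes == 1L),
    n_single_species = sum(n_species == 1L),
    single_species_fraction = 100 * sum(n_species == 1L) / length(partition),
    by_species_count = setNames(as.integer(hist), names(hist)),
    per_species = per_species
  ), class = "cluster_census")
}

#' @export
print.cluster_census <- function(x, ...) {
  cat("<cluster_census> ", x$total, " clusters; ",
      x$n_singleton, " singletons; ",
      x$n_single_species, " single-species (",
      sprintf("%.2f", x$single_species_fraction), "%)\n", sep = "")
  invisible(x)
}

#' Mean pairwise annotation similarity within a cluster
#'
#' Functional-coherence score for a cluster: the mean Jaccard index of GO
#' (or GO-slim) term sets over all pairs of annotated members. Members
#' without terms are excluded; with fewer than two annotated members the
#' score is undefined and reported as `NA`.
#'
#' @param members Character vector of cluster member ids.
#' @param annotations Named list mapping protein id to a character vector of
#'   term ids.
#' @return Score in \[0, 1\], or `NA` when fewer than two members are
#'   annotated.
#' @export
go_similarity <- function(members, annotations) {
  sets <- annotations[intersect(members, names(annotations))]
  sets <- Filter(function(s) length(s) > 0L, sets)
  n <- length(sets)
  if (n < 2L) return(NA_real_)
  total <- 0
  count <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      u <- union(sets[[i]], sets[[j]])
      total <- total + length(intersect(sets[[i]], sets[[j]])) / length(u)
      count <- count + 1L
    }
  }
  total / count
}

#' Coefficient of determination
#'
#' Squared Pearson correlation, used for the correlations reported between
#' proteome size and plastid-targeted counts.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return R-squared in \[0, 1\].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 points are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  stats::cor(x, y)^2
}
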