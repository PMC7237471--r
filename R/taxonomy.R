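#' Construct a species taxonomy
#'
#' A taxonomy maps each species code to an ordered lineage
#' (clade > subclade > family) and names one distinguished outgroup species.
#' It drives the semi-conserved classification rules: plastid targeting
#' confined to a clade, subclade, or family.
#'
#' @param species `data.frame` with columns `species`, `clade`, `subclade`,
#'   `family`.
#' @param outgroup Species code of the outgroup (a one-species clade).
#' @return An object of class `taxonomy`.
#' @export
taxonomy <- function(species, outgroup) {
  stopifnot(is.data.frame(species),
            all(c("species", "clade", "subclade", "family") %in% names(species)))
  if (anyDuplicated(species$species)) stop("duplicate species codes in taxonomy")
  missing_clade <- species$species[is.na(species$clade) | !nzchar(species$clade)]
  if (length(missing_clade) > 0L) {
    stop("species with no clade: ", paste(missing_clade, collapse = ", "))
  }
  if (!outgroup %in% species$species) stop("outgroup '", outgroup, "' not in species table")
  structure(list(species = species, outgroup = outgroup), class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$species), " species, outgroup: ", x$outgroup, "\n", sep = "")
  print(x$species, row.names = FALSE)
  invisible(x)
}

#' Default 15-species angiosperm taxonomy
#'
#' The built-in taxonomy covers the fifteen angiosperm proteomes of the
#' reference study: six monocots, eight eudicots, and *Amborella trichopoda*
#' as the early-diverging outgroup. Subclade and family labels follow the
#' usual botanical groupings (commelinid grasses in Poaceae, rosids split
#' into Rosaceae/Fabaceae/..., tomato as the sole asterid).
#'
#' @return A `taxonomy` object with 15 species.
#' @export
default_taxonomy <- function() {
  sp <- read.table(text = "
species clade    subclade    family
Atr     amborella amborellales Amborellaceae
Aam     monocot  alismatid   Araceae
Bdi     monocot  commelinid  Poaceae
Osa     monocot  commelinid  Poaceae
Pvi     monocot  commelinid  Poaceae
Sit     monocot  commelinid  Poaceae
Sbi     monocot  commelinid  Poaceae
Ath     eudicot  rosid       Brassicaceae
Fve     eudicot  rosid       Rosaceae
Gma     eudicot  rosid       Fabaceae
Mdo     eudicot  rosid       Rosaceae
Ptr     eudicot  rosid       Salicaceae
Ppe     eudicot  rosid       Rosaceae
Sly     eudicot  asterid     Solanaceae
Vvi     eudicot  rosid       Vitaceae
", header = TRUE, stringsAsFactors = FALSE)
  taxonomy(sp, outgroup = "Atr")
}

#' Read a taxonomy configuration file
#'
#' The configuration is a YAML mapping with an `outgroup` key and a
#' `species` mapping of species code to `{clade, subclade, family}`.
#'
#' @param path Path to a YAML taxonomy file.
#' @return A `taxonomy` object.
#' @seealso [write_taxonomy()], [default_taxonomy()]
#' @export
read_taxonomy <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species) || length(cfg$species) == 0L) {
    stop("taxonomy config has no species")
  }
  rows <- lapply(names(cfg$species), function(code) {
    entry <- cfg$species[[code]]
    if (is.null(entry$clade)) stop("species with no clade: ", code)
    data.frame(species = code, clade = entry$clade,
               subclade = entry$subclade %||% entry$clade,
               family = entry$family %||% entry$subclade %||% entry$clade,
               stringsAsFactors = FALSE)
  })
  if (is.null(cfg$outgroup)) stop("taxonomy config has no outgroup")
  taxonomy(do.call(rbind, rows), outgroup = cfg$outgroup)
}

#' Write a taxonomy configuration file
#'
#' @param tax A `taxonomy` object.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy"))
  species <- lapply(seq_len(nrow(tax$species)), function(i) {
    list(clade = tax$species$clade[i],
         subclade = tax$species$subclade[i],
         family = tax$species$family[i])
  })
  names(species) <- tax$species$species
  yaml::write_yaml(list(outgroup = tax$outgroup, species = species), path)
  invisible(path)
}

#' Look up the lineage of a species
#'
#' @param tax A `taxonomy` object.
#' @param species Species code(s).
#' @param level Lineage level: `"clade"`, `"subclade"`, or `"family"`.
#' @return Character vector of lineage labels; errors on unknown species.
#' @export
lineage_of <- function(tax, species, level = c("clade", "subclade", "family")) {
  stopifnot(inherits(tax, "taxonomy"))
  level <- match.arg(level)
  idx <- match(species, tax$species$species)
  if (anyNA(idx)) {
    stop("species absent from taxonomy: ",
         paste(species[is.na(idx)], collapse = ", "))
  }
  tax$species[[level]][idx]
}

#' List the species belonging to a lineage label
#'
#' Searches all three lineage levels, so `species_in(tax, "monocot")` and
#' `species_in(tax, "Poaceae")` both work.
#'
#' @param tax A `taxonomy` object.
#' @param label Lineage label.
#' @return Character vector of species codes (possibly empty).
#' @export
species_in <- function(tax, label) {
  stopifnot(inherits(tax, "taxonomy"))
  sp <- tax$species
  sp$species[sp$clade == label | sp$subclade == label | sp$family == label]
}
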