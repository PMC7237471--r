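#' Read a protein FASTA file
#'
#' Parses one FASTA file into a protein-record table. Sequences are
#' uppercased and a single trailing stop character (`*`) is stripped; internal
#' stops are left untouched so that malformed gene models remain visible to
#' downstream filters. The species of origin is normally supplied per file;
#' alternatively a capture regex can pull it from the header.
#'
#' @param path Path to a FASTA file.
#' @param species Species code attached to every record in the file. Ignored
#'   when `header_regex` is given.
#' @param header_regex Optional regular expression with one capture group,
#'   applied to each full header line to extract the species code.
#' @return A `data.frame` with columns `id`, `species`, `sequence`, `length`.
#'   The `id` is the first whitespace-delimited token of the header and must
#'   be unique within the file.
#' @seealso [write_fasta()], [preprocess_proteome()]
#' @export
read_fasta <- function(path, species = NA_character_, header_regex = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (!is.null(header_regex)) {
    m <- regmatches(headers, regexec(header_regex, headers))
    sp <- vapply(m, function(x) if (length(x) >= 2L) x[[2L]] else NA_character_,
                 character(1))
    if (anyNA(sp)) stop("header_regex failed to match ", sum(is.na(sp)), " header(s)")
  } else {
    sp <- rep(as.character(species), length(ids))
  }
  data.frame(id = ids, species = sp, sequence = unname(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records Protein-record `data.frame` as returned by [read_fasta()]
#'   or [simulate_corpus()] (columns `id` and `sequence` are used).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Species lookup from a protein-record table
#'
#' @param records Protein-record `data.frame` with `id` and `species` columns.
#' @return Named character vector mapping protein id to species code.
#' @export
species_lookup <- function(records) {
  setNames(records$species, records$id)
}

#' Write a cluster membership table
#'
#' Emits the long TSV layout used for cluster exchange: one row per member
#' with columns `cluster_id`, `protein_id`, `species`, `plastid_flag`.
#'
#' @param partition Named list of character vectors (cluster id -> member ids).
#' @param species_of Named character vector mapping protein id to species.
#' @param plastid_set Character vector of plastid-predicted protein ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(partition, species_of, plastid_set = character(), path) {
  ids <- unlist(partition, use.names = FALSE)
  tab <- data.frame(
    cluster_id = rep(names(partition), lengths(partition)),
    protein_id = ids,
    species = unname(species_of[ids]),
    plastid_flag = ids %in% plastid_set,
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cluster membership table
#'
#' Inverse of [write_cluster_table()].
#'
#' @param path Path to a cluster TSV.
#' @return Named list of member-id vectors, with attributes `species_of`
#'   (named character vector) and `plastid_set` (character vector).
#' @export
read_cluster_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character", "logical"))
  part <- split(tab$protein_id, tab$cluster_id)
  part <- part[unique(tab$cluster_id)]
  attr(part, "species_of") <- setNames(tab$species, tab$protein_id)
  attr(part, "plastid_set") <- tab$protein_id[tab$plastid_flag]
  part
}
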