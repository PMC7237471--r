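#' Read a subcellular-predictor output table
#'
#' Converts native predictor output into binary plastid / non-plastid calls.
#' Three dialects are supported:
#'
#' * `"targetp"` — TargetP v1.1 plain-text output: a whitespace table whose
#'   columns are name, length, cTP, mTP, SP, other, Loc, RC. The location
#'   code `C` (chloroplast) maps to a plastid call; every other code (`M`,
#'   `S`, `_`, `*`, ...) maps to non-plastid. Ruler and comment lines are
#'   skipped.
#' * `"localizer"` — Localizer v1.0.2 summary table: tab-separated with the
#'   chloroplast column holding `Y (score)` for a positive call or `-`
#'   otherwise.
#' * `"generic"` — a TSV of `protein_id<TAB>predictor<TAB>call` with call in
#'   `{plastid, other}`; this covers predictors whose native output is not
#'   parsed (MultiLoc2, PredSL, PCLR, WoLF PSORT, ...).
#'
#' @param path Path to the predictor output.
#' @param dialect One of `"targetp"`, `"localizer"`, `"generic"`.
#' @param predictor Predictor name to attach to the calls; defaults to
#'   `"TargetP"` / `"Localizer"` for the native dialects and is taken from the
#'   file for the generic dialect.
#' @return A long `data.frame` with columns `protein`, `predictor`, `plastid`
#'   (logical). Combine fragments with [call_table()].
#' @export
read_predictor_table <- function(path, dialect = c("targetp", "localizer", "generic"),
                                 predictor = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("predictor file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- switch(dialect,
    targetp = parse_targetp(lines, predictor %||% "TargetP"),
    localizer = parse_localizer(lines, predictor %||% "Localizer"),
    generic = parse_generic_calls(lines)
  )
  dup <- duplicated(out[c("protein", "predictor")])
  if (any(dup)) {
    key <- paste(out$protein, out$predictor)
    conflict <- vapply(split(out$plastid, key), function(x) length(unique(x)) > 1L,
                       logical(1))
    if (any(conflict)) {
      stop("conflicting duplicate call(s) for: ",
           paste(head(names(conflict)[conflict], 5L), collapse = ", "))
    }
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_targetp <- function(lines, predictor) {
  lines <- trimws(lines)
  keep <- nzchar(lines) & !grepl("^[-#=]", lines)
  fields <- strsplit(lines[keep], "\\s+")
  rows <- Filter(function(f) length(f) >= 8L && !is.na(suppressWarnings(as.numeric(f[[2L]]))),
                 fields)
  if (length(rows) == 0L) stop("no TargetP data rows found")
  data.frame(
    protein = vapply(rows, `[[`, character(1), 1L),
    predictor = predictor,
    plastid = vapply(rows, `[[`, character(1), 7L) == "C",
    stringsAsFactors = FALSE
  )
}

parse_localizer <- function(lines, predictor) {
  keep <- nzchar(trimws(lines)) & !grepl("^[-#=]", lines)
  fields <- strsplit(lines[keep], "\t")
  rows <- Filter(function(f) length(f) >= 2L && grepl("^(Y|-)", trimws(f[[2L]])),
                 fields)
  if (length(rows) == 0L) stop("no Localizer data rows found")
  data.frame(
    protein = vapply(rows, function(f) strsplit(trimws(f[[1L]]), "\\s+")[[1L]][1L],
                     character(1)),
    predictor = predictor,
    plastid = grepl("^Y", vapply(rows, function(f) trimws(f[[2L]]), character(1))),
    stringsAsFactors = FALSE
  )
}

parse_generic_calls <- function(lines) {
  keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
  fields <- strsplit(lines[keep], "\t")
  if (length(fields) > 0L && identical(tolower(trimws(fields[[1L]][1L])), "protein")) {
    fields <- fields[-1L]
  }
  if (length(fields) == 0L) stop("no generic call rows found")
  nfield <- lengths(fields)
  if (any(nfield != 3L)) {
    stop("generic call table requires 3 tab-separated columns; offending line ",
         which(nfield != 3L)[1L])
  }
  call <- tolower(vapply(fields, `[[`, character(1), 3L))
  bad <- setdiff(unique(call), c("plastid", "other"))
  if (length(bad) > 0L) {
    stop("unknown call value(s): ", paste(bad, collapse = ", "),
         " (expected 'plastid' or 'other')")
  }
  data.frame(
    protein = vapply(fields, `[[`, character(1), 1L),
    predictor = vapply(fields, `[[`, character(1), 2L),
    plastid = call == "plastid",
    stringsAsFactors = FALSE
  )
}

#' Assemble a call table from long-format call fragments
#'
#' A call table is the package's central predictor container: a logical
#' matrix with one row per protein and one column per predictor, `TRUE`
#' meaning a plastid call.
#'
#' @param ... Long call `data.frame`s (columns `protein`, `predictor`,
#'   `plastid`) as produced by [read_predictor_table()] or a single such
#'   data.frame.
#' @param fill Value used for (protein, predictor) cells not present in any
#'   fragment; the default `NA` makes missing calls visible, `FALSE`
#'   treats absence as a non-plastid call.
#' @return Logical matrix (proteins x predictors) of class `call_table`.
#' @export
call_table <- function(..., fill = NA) {
  frags <- list(...)
  long <- do.call(rbind, frags)
  stopifnot(all(c("protein", "predictor", "plastid") %in% names(long)))
  key <- paste(long$protein, long$predictor, sep = "\r")
  conflict <- vapply(split(long$plastid, key), function(x) length(unique(x)) > 1L,
                     logical(1))
  if (any(conflict)) {
    stop("conflicting duplicate call(s) for: ",
         paste(head(sub("\r", " / ", names(conflict)[conflict]), 5L), collapse = ", "))
  }
  long <- long[!duplicated(key), , drop = FALSE]
  proteins <- unique(long$protein)
  predictors <- unique(long$predictor)
  m <- matrix(fill, nrow = length(proteins), ncol = length(predictors),
              dimnames = list(proteins, predictors))
  m[cbind(match(long$protein, proteins), match(long$predictor, predictors))] <-
    long$plastid
  class(m) <- c("call_table", class(m))
  m
}

#' Write a call table as a generic call TSV
#'
#' @param calls A `call_table` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(calls, path) {
  long <- data.frame(
    protein = rep(rownames(calls), ncol(calls)),
    predictor = rep(colnames(calls), each = nrow(calls)),
    call = ifelse(as.vector(calls), "plastid", "other"),
    stringsAsFactors = FALSE
  )
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
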