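#' Enumerate all k-of-n consensus workflows over a predictor panel
#'
#' A consensus workflow is a non-empty predictor subset S together with an
#' accept threshold m in 1..|S|: a protein is called plastid-targeted when at
#' least m members of S call it plastid. Every (subset, threshold) pair is
#' enumerated, giving `n * 2^(n-1)` workflows for n predictors (80 for the
#' five-predictor panel of the reference evaluation). Ordering is
#' deterministic: by subset size, then lexicographic subset, then threshold.
#'
#' @param predictor_names Character vector of predictor names (>= 1).
#' @return `data.frame` with columns `workflow` (id), `predictors`
#'   (`+`-joined subset, lexicographic order), `size`, and `threshold`.
#' @export
enumerate_workflows <- function(predictor_names) {
  predictor_names <- unique(as.character(predictor_names))
  n <- length(predictor_names)
  if (n == 0L) stop("at least one predictor is required")
  sorted <- sort(predictor_names)
  rows <- list()
  for (size in seq_len(n)) {
    subsets <- utils::combn(sorted, size, simplify = FALSE)
    ord <- order(vapply(subsets, paste, character(1), collapse = "\r"))
    for (s in subsets[ord]) {
      for (m in seq_len(size)) {
        rows[[length(rows) + 1L]] <- data.frame(
          predictors = paste(s, collapse = "+"), size = size, threshold = m,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(workflow = seq_len(nrow(out)), out)
  out
}

#' Apply one consensus workflow to a call table
#'
#' @param predictors Character vector of predictor names forming the subset,
#'   or a `+`-joined string as found in [enumerate_workflows()] output.
#' @param threshold Minimum number of plastid votes to accept.
#' @param calls A `call_table` logical matrix.
#' @return Named logical vector: `TRUE` where at least `threshold` of the
#'   subset's predictors call plastid.
#' @export
apply_workflow <- function(predictors, threshold, calls) {
  if (length(predictors) == 1L && grepl("+", predictors, fixed = TRUE)) {
    predictors <- strsplit(predictors, "+", fixed = TRUE)[[1L]]
  }
  missing <- setdiff(predictors, colnames(calls))
  if (length(missing) > 0L) {
    stop("predictor column(s) missing from call table: ",
         paste(missing, collapse = ", "))
  }
  if (threshold < 1 || threshold > length(predictors)) {
    stop("threshold must be in 1..", length(predictors))
  }
  sub <- calls[, predictors, drop = FALSE]
  if (anyNA(sub)) stop("call table has missing calls for scored predictors")
  votes <- rowSums(sub)
  setNames(votes >= threshold, rownames(calls))
}

#' Evaluate and rank every consensus workflow against experimental labels
#'
#' Runs the exhaustive k-of-n sweep: every workflow from
#' [enumerate_workflows()] is applied to the call table, scored against the
#' label table, and ranked by MCC (descending), with ties broken by accuracy,
#' then sensitivity, then enumeration order, so ranking tables are
#' reproducible. When a stratification is supplied (e.g. monocot vs eudicot,
#' or GFP vs MS evidence), the evaluation is repeated within each stratum and,
#' for a two-level stratification, rows of between-stratum differences
#' (first level minus second) are appended. Strata with no positives or no
#' negatives are still scored, under the zero-marginal convention of
#' [classification_stats()], and carry `degenerate = TRUE`.
#'
#' @param calls A `call_table` logical matrix.
#' @param labels `data.frame` with columns `protein` and `plastid` (logical
#'   experimental label); must cover every scored protein.
#' @param strata Optional named character vector mapping protein id to
#'   stratum.
#' @return `data.frame` with one row per workflow (and stratum): workflow
#'   spec columns, confusion counts, statistics, `rank`, and `stratum`
#'   (`"all"` when unstratified; `"<A>-<B>"` difference rows have NA counts).
#' @export
evaluate_workflows <- function(calls, labels, strata = NULL) {
  stopifnot(is.matrix(calls))
  truth <- setNames(labels$plastid, labels$protein)
  specs <- enumerate_workflows(colnames(calls))
  eval_one_stratum <- function(proteins, stratum_label) {
    sub <- calls[proteins, , drop = FALSE]
    stats <- lapply(seq_len(nrow(specs)), function(i) {
      pred <- apply_workflow(specs$predictors[i], specs$threshold[i], sub)
      classification_stats(confusion_from_calls(pred, truth))
    })
    out <- cbind(specs, do.call(rbind, stats))
    ord <- order(-out$mcc, -out$acc, -out$se, out$workflow)
    out$rank <- NA_integer_
    out$rank[ord] <- seq_len(nrow(out))
    out$stratum <- stratum_label
    out[ord, , drop = FALSE]
  }
  proteins <- intersect(rownames(calls), names(truth))
  if (length(proteins) == 0L) stop("no labelled proteins in call table")
  if (is.null(strata)) {
    out <- eval_one_stratum(proteins, "all")
    rownames(out) <- NULL
    return(out)
  }
  strata <- strata[proteins]
  levels <- unique(strata[!is.na(strata)])
  parts <- lapply(levels, function(lv) eval_one_stratum(proteins[strata == lv], lv))
  out <- do.call(rbind, parts)
  if (length(levels) == 2L) {
    a <- parts[[1L]][order(parts[[1L]]$workflow), , drop = FALSE]
    b <- parts[[2L]][order(parts[[2L]]$workflow), , drop = FALSE]
    diff <- a
    for (col in c("se", "sp_precision", "sp_conventional", "mcc", "acc")) {
      diff[[col]] <- a[[col]] - b[[col]]
    }
    diff[c("tp", "fp", "tn", "fn")] <- NA_real_
    diff$rank <- NA_integer_
    diff$degenerate <- a$degenerate | b$degenerate
    diff$stratum <- paste0(levels[1L], "-", levels[2L])
    out <- rbind(out, diff)
  }
  rownames(out) <- NULL
  out
}

#' Convert precision-style specificity to a false-positive rate
#'
#' Published cTP evaluations report precision (`tp/(tp+fp)`) as
#' "specificity", which is not a generative parameter: it depends on class
#' prevalence. For simulation, this helper converts a published (SE, SP) pair
#' plus class sizes into the per-negative false-positive rate
#' `FPR = fp / n_neg = SE * n_pos * (1 - SP) / (SP * n_neg)`.
#'
#' @param se Sensitivity in (0, 1].
#' @param sp Precision-style specificity in (0, 1].
#' @param n_pos,n_neg Class sizes defining the prevalence.
#' @return False-positive rate in \[0, 1\].
#' @export
fpr_from_precision <- function(se, sp, n_pos, n_neg) {
  if (sp <= 0 || sp > 1) stop("sp must be in (0, 1]")
  fpr <- se * n_pos * (1 - sp) / (sp * n_neg)
  min(max(fpr, 0), 1)
}
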