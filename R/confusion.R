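#' Construct a confusion matrix
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts.
#' @return A named integer vector of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  cm <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(cm))) stop("confusion matrix cells must not be NA")
  if (any(cm < 0)) stop("confusion matrix cells must be non-negative")
  structure(cm, class = "confusion_matrix")
}

#' Confusion matrix of a binary prediction against labels
#'
#' @param predicted Named logical vector of plastid calls.
#' @param truth Named logical vector of true labels; names must cover
#'   `names(predicted)`.
#' @return A `confusion_matrix`.
#' @export
confusion_from_calls <- function(predicted, truth) {
  truth <- truth[names(predicted)]
  if (anyNA(truth)) stop("labels missing for ", sum(is.na(truth)), " scored protein(s)")
  confusion_matrix(
    tp = sum(predicted & truth), fp = sum(predicted & !truth),
    tn = sum(!predicted & !truth), fn = sum(!predicted & truth)
  )
}

#' Binary-classification statistics for plastid-targeting evaluation
#'
#' Computes the four statistics used throughout the cTP-prediction
#' evaluation: sensitivity `SE = tp/(tp+fn)`, the precision-style specificity
#' `SP = tp/(tp+fp)` conventional in this literature (i.e. positive
#' predictive value, *not* `tn/(tn+fp)`), the Matthews correlation
#' coefficient, and overall accuracy `ACC = (tp+tn)/total`. Because exhaustive
#' workflow sweeps regularly produce degenerate matrices, zero-denominator
#' statistics are defined as 0 (MCC when any marginal is zero; SE/SP when
#' their denominator is zero) and flagged rather than raising an error. The
#' conventional true-negative-rate specificity is also reported, as
#' `sp_conventional`, to avoid silent confusion between the two conventions.
#'
#' @param cm A `confusion_matrix`, or `tp` given as four separate counts.
#' @param fp,tn,fn Cell counts when `cm` is given piecewise.
#' @return One-row `data.frame` with columns `tp`, `fp`, `tn`, `fn`, `se`,
#'   `sp_precision`, `sp_conventional`, `mcc`, `acc`, `degenerate` (logical: some
#'   statistic had a zero denominator).
#' @export
classification_stats <- function(cm, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.null(fp)) cm <- confusion_matrix(cm, fp, tn, fn)
  if (!inherits(cm, "confusion_matrix")) cm <- do.call(confusion_matrix, as.list(cm))
  tp <- as.numeric(cm[["tp"]]); fp <- as.numeric(cm[["fp"]])
  tn <- as.numeric(cm[["tn"]]); fn <- as.numeric(cm[["fn"]])
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix")
  se <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp_precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  sp_conv <- if (tn + fp > 0) tn / (tn + fp) else 0
  marg <- c(tp + fn, tp + fp, tn + fn, tn + fp)
  mcc <- if (any(marg == 0)) 0 else (tp * tn - fp * fn) / sqrt(prod(marg))
  degenerate <- any(marg == 0)
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
             se = se, sp_precision = sp_precision, sp_conventional = sp_conv,
             mcc = mcc, acc = (tp + tn) / total, degenerate = degenerate)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Reconstruct a confusion matrix from published rounded statistics
#'
#' Published evaluations often print only SE, precision-style SP, and the
#' class sizes. This utility inverts those: `tp = round(SE * n_pos)`,
#' predicted positives `= round(tp / SP)`, then `fp`, `fn`, `tn` follow by
#' subtraction (half-up rounding throughout). Cells are clamped at zero with
#' a consistency flag if clamping occurred.
#'
#' Because the printed statistics are rounded, the point reconstruction can
#' miss the original matrix by a count or two, which occasionally flips the
#' last printed digit of MCC or ACC. When `envelope = TRUE` the function
#' therefore also enumerates every `(tp, predicted-positive)` pair consistent
#' with the printed SE/SP at `digits` decimals and reports the resulting
#' MCC and ACC ranges, so one can check whether a printed value is attainable
#' at all under the stated class sizes.
#'
#' @param se Printed sensitivity, in (0, 1].
#' @param sp Printed precision-style specificity, in (0, 1].
#' @param n_pos,n_neg Positive and negative class sizes.
#' @param digits Precision of the printed statistics (default 2 decimals).
#' @param envelope Also compute the rounding-consistency envelope?
#' @return A list with elements `cm` (the point `confusion_matrix`), `stats`
#'   (its [classification_stats()]), `clamped` (logical), and when requested
#'   `mcc_range` / `acc_range` (numeric length-2 envelopes).
#' @export
reconstruct_confusion <- function(se, sp, n_pos, n_neg, digits = 2,
                                  envelope = FALSE) {
  if (is.na(se) || is.na(sp) || se <= 0 || se > 1) stop("se must be in (0, 1]")
  if (sp <= 0 || sp > 1) stop("sp must be in (0, 1] (sp = 0 is not invertible)")
  if (n_pos <= 0 || n_neg <= 0) stop("class sizes must be positive")
  tp <- round_half_up(se * n_pos)
  pp <- round_half_up(tp / sp)
  fp <- pp - tp
  fn <- n_pos - tp
  tn <- n_neg - fp
  clamped <- any(c(tp, fp, fn, tn) < 0)
  cm <- confusion_matrix(max(tp, 0), max(fp, 0), max(tn, 0), max(fn, 0))
  out <- list(cm = cm, stats = classification_stats(cm), clamped = clamped)
  if (envelope) {
    tp_cand <- 0:n_pos
    tp_cand <- tp_cand[round_half_up(tp_cand / n_pos, digits) == round_half_up(se, digits)]
    mccs <- numeric(0); accs <- numeric(0)
    for (t in tp_cand) {
      pp_lo <- max(t, ceiling(t / (sp + 0.5 * 10^-digits)))
      pp_hi <- min(t + n_neg, floor(t / max(sp - 0.5 * 10^-digits, 1e-12)))
      for (p in seq_len(max(0L, pp_hi - pp_lo + 1L)) + pp_lo - 1L) {
        if (p < 1) next
        if (round_half_up(t / p, digits) != round_half_up(sp, digits)) next
        s <- classification_stats(confusion_matrix(t, p - t, n_neg - (p - t), n_pos - t))
        mccs <- c(mccs, s$mcc); accs <- c(accs, s$acc)
      }
    }
    out$mcc_range <- if (length(mccs)) range(mccs) else c(NA_real_, NA_real_)
    out$acc_range <- if (length(accs)) range(accs) else c(NA_real_, NA_real_)
  }
  out
}
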