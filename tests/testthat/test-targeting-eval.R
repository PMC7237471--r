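test_that("classification statistics implement the published conventions", {
  # values matching the monocot GFP evaluation of TargetP
  s <- classification_stats(confusion_matrix(tp = 100, fp = 41, tn = 599, fn = 61))
  expect_equal(round(s$se, 2), 0.62)
  expect_equal(round(s$sp_precision, 2), 0.71)
  expect_equal(round(s$mcc, 2), 0.59)
  expect_equal(round(s$acc, 2), 0.87)
  expect_equal(s$sp_conventional, 599 / 640)

  perfect <- classification_stats(confusion_matrix(10, 0, 10, 0))
  expect_equal(unlist(perfect[c("se", "sp_precision", "mcc", "acc")]),
               c(se = 1, sp_precision = 1, mcc = 1, acc = 1))

  all_pos <- classification_stats(confusion_matrix(10, 10, 0, 0))
  expect_equal(all_pos$acc, 0.5)
  expect_equal(all_pos$mcc, 0)
  expect_true(all_pos$degenerate)

  expect_error(classification_stats(confusion_matrix(0, 0, 0, 0)), "empty")
  expect_error(confusion_matrix(-1, 0, 0, 0), "non-negative")
})

test_that("MCC is invariant under the tp/tn, fp/fn swap", {
  set.seed(21)
  for (i in 1:50) {
    cm <- sample.int(200, 4)
    a <- classification_stats(confusion_matrix(cm[1], cm[2], cm[3], cm[4]))
    b <- classification_stats(confusion_matrix(cm[3], cm[4], cm[1], cm[2]))
    expect_equal(a$mcc, b$mcc)
  }
})

test_that("MCC of label-permuted classifiers concentrates near zero", {
  set.seed(31)
  n <- 400
  truth <- rep(c(TRUE, FALSE), c(100, 300))
  mccs <- replicate(1000, {
    pred <- sample(truth)
    classification_stats(confusion_from_calls(setNames(pred, seq_len(n)),
                                              setNames(truth, seq_len(n))))$mcc
  })
  expect_lt(abs(mean(mccs)), 0.02)
  expect_gt(mean(abs(mccs) < 0.15), 0.99)
})

test_that("workflow enumeration matches the closed form n * 2^(n-1)", {
  for (n in 1:8) {
    wf <- enumerate_workflows(letters[seq_len(n)])
    expect_equal(nrow(wf), n * 2^(n - 1))
  }
  expect_equal(nrow(enumerate_workflows(c("TargetP", "PredSL", "Localizer",
                                          "Multiloc2", "PCLR"))), 80L)
  expect_equal(nrow(enumerate_workflows("TargetP")), 1L)
  expect_error(enumerate_workflows(character(0)), "at least one")
  # deterministic ordering: size, then lexicographic subset, then threshold
  wf <- enumerate_workflows(c("b", "a", "c"))
  expect_equal(wf$predictors[1:6], c("a", "b", "c", "a+b", "a+b", "a+c"))
  expect_equal(wf$threshold[4:5], c(1L, 2L))
})

test_that("k-of-n voting agrees with a brute-force vote count", {
  calls <- matrix(FALSE, 2, 2, dimnames = list(c("p1", "p2"), c("A", "B")))
  calls["p1", "A"] <- TRUE
  expect_false(apply_workflow(c("A", "B"), 2, calls)[["p1"]])
  expect_true(apply_workflow(c("A", "B"), 1, calls)[["p1"]])
  expect_error(apply_workflow(c("A", "Z"), 1, calls), "Z")

  set.seed(41)
  big <- matrix(runif(800) < 0.4, 200, 4,
                dimnames = list(sprintf("q%03d", 1:200), c("W", "X", "Y", "Z")))
  specs <- enumerate_workflows(colnames(big))
  for (i in seq_len(nrow(specs))) {
    preds <- strsplit(specs$predictors[i], "+", fixed = TRUE)[[1]]
    expect_identical(apply_workflow(specs$predictors[i], specs$threshold[i], big),
                     oracle_vote(big, preds, specs$threshold[i]))
  }
})

test_that("raising the threshold shrinks the predicted-positive set", {
  set.seed(43)
  calls <- matrix(runif(500) < 0.5, 100, 5,
                  dimnames = list(sprintf("p%03d", 1:100), letters[1:5]))
  for (subset in list(c("a", "b"), c("a", "c", "e"), letters[1:5])) {
    prev <- NULL
    for (m in seq_along(subset)) {
      cur <- names(which(apply_workflow(subset, m, calls)))
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("exhaustive evaluation matches hand-built confusion matrices", {
  set.seed(47)
  n <- 20
  ids <- sprintf("p%02d", seq_len(n))
  calls <- matrix(runif(2 * n) < 0.5, n, 2, dimnames = list(ids, c("A", "B")))
  labels <- data.frame(protein = ids, plastid = runif(n) < 0.4)
  res <- evaluate_workflows(calls, labels)
  expect_equal(nrow(res), 4L)
  truth <- setNames(labels$plastid, labels$protein)
  for (i in seq_len(nrow(res))) {
    preds <- strsplit(res$predictors[i], "+", fixed = TRUE)[[1]]
    pred <- oracle_vote(calls, preds, res$threshold[i])
    expect_equal(res$tp[i], sum(pred & truth))
    expect_equal(res$fn[i], sum(!pred & truth))
  }
  expect_equal(res$rank, seq_len(4L))
  expect_true(all(diff(res$mcc) <= 1e-12))
})

test_that("workflows built only from a dominated predictor never beat the dominant one", {
  # A is correct wherever B is, and on strictly more proteins
  ids <- sprintf("p%02d", 1:40)
  truth <- rep(c(TRUE, FALSE), each = 20)
  b_call <- c(rep(TRUE, 10), rep(FALSE, 10), rep(FALSE, 15), rep(TRUE, 5))
  a_call <- c(rep(TRUE, 16), rep(FALSE, 4), rep(FALSE, 18), rep(TRUE, 2))
  calls <- cbind(A = a_call, B = b_call)
  rownames(calls) <- ids
  res <- evaluate_workflows(calls, data.frame(protein = ids, plastid = truth))
  mcc_a <- res$mcc[res$predictors == "A"]
  expect_true(all(res$mcc[res$predictors == "B"] < mcc_a))
})

test_that("stratified evaluation reports per-stratum tables and their difference", {
  set.seed(53)
  ids <- sprintf("p%03d", 1:200)
  calls <- matrix(runif(400) < 0.5, 200, 2, dimnames = list(ids, c("A", "B")))
  labels <- data.frame(protein = ids, plastid = runif(200) < 0.3)
  strata <- setNames(rep(c("monocot", "eudicot"), each = 100), ids)
  res <- evaluate_workflows(calls, labels, strata = strata)
  expect_setequal(unique(res$stratum), c("monocot", "eudicot", "monocot-eudicot"))
  per <- split(res, res$stratum)
  expect_equal(nrow(per$monocot), 4L)
  m <- per$monocot[order(per$monocot$workflow), ]
  e <- per$eudicot[order(per$eudicot$workflow), ]
  d <- per$`monocot-eudicot`[order(per$`monocot-eudicot`$workflow), ]
  expect_equal(d$mcc, m$mcc - e$mcc)
  expect_true(all(is.na(d$tp)))
})

test_that("a stratum with no positives is flagged but still scored", {
  ids <- sprintf("p%02d", 1:20)
  calls <- matrix(c(rep(TRUE, 10), rep(FALSE, 10)), 20, 1,
                  dimnames = list(ids, "A"))
  labels <- data.frame(protein = ids, plastid = FALSE)
  res <- evaluate_workflows(calls, labels)
  expect_true(all(res$degenerate))
  expect_equal(res$mcc, 0)
})

test_that("confusion reconstruction applies the stated rounding rules", {
  r <- reconstruct_confusion(0.62, 0.71, 161, 640)
  expect_equal(unclass(r$cm), c(tp = 100, fp = 41, tn = 599, fn = 61),
               ignore_attr = TRUE)
  expect_false(r$clamped)

  perfect <- reconstruct_confusion(1, 1, 10, 10)
  expect_equal(unclass(perfect$cm), c(tp = 10, fp = 0, tn = 10, fn = 0),
               ignore_attr = TRUE)

  # PCLR monocot row: reconstructed matrix reproduces the printed MCC
  pclr <- reconstruct_confusion(0.75, 0.56, 161, 640)
  expect_equal(round(pclr$stats$mcc, 2), 0.54)

  expect_error(reconstruct_confusion(0.5, 0, 10, 10), "sp")
  expect_error(reconstruct_confusion(0, 0.5, 10, 10), "se")
})

test_that("statistics and reconstruction round-trip at printed precision", {
  set.seed(59)
  for (i in 1:100) {
    se <- round(runif(1, 0.3, 0.95), 2)
    sp <- round(runif(1, 0.3, 0.95), 2)
    r <- reconstruct_confusion(se, sp, 161, 640)
    if (r$clamped) next
    expect_equal(round(r$stats$se, 2), se)
    # SP granularity is 1/(predicted positives); at n_pos = 161 that can
    # exceed half a printed unit, so SP round-trips to within one unit in
    # the last printed digit rather than exactly
    expect_lte(abs(round(r$stats$sp_precision, 2) - sp), 0.01 + 1e-9)
    r2 <- reconstruct_confusion(se, sp, 489, 2432)
    if (!r2$clamped) {
      expect_equal(round(r2$stats$se, 2), se)
      expect_equal(round(r2$stats$sp_precision, 2), sp)
    }
  }
})

test_that("simulated calls recover the generating sensitivity", {
  truth <- data.frame(id = sprintf("p%03d", 1:900),
                      plastid = rep(c(TRUE, FALSE), c(500, 400)))
  calls <- simulate_calls(truth, data.frame(name = "P", se = 0.7, fpr = 0.1),
                          seed = 61)
  est <- sum(calls[truth$plastid, 1]) / 500
  ci <- qnorm(c(0.025, 0.975), 0.7, sqrt(0.7 * 0.3 / 500))
  expect_gt(est, ci[1])
  expect_lt(est, ci[2])
})

test_that("precision-to-FPR conversion is consistent with reconstruction", {
  fpr <- fpr_from_precision(0.62, 0.71, 161, 640)
  r <- reconstruct_confusion(0.62, 0.71, 161, 640)
  expect_equal(fpr, r$stats$fp / 640, tolerance = 0.01)
})
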