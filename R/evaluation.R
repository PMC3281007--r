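#' ROC curve points and AUC
#'
#' Sweeps the decision threshold over the unique score values (ties grouped;
#' prediction is positive when score >= threshold) and integrates the curve
#' by the trapezoidal rule.
#'
#' @param scores numeric scores, larger meaning more likely positive
#' @param labels logical or 0/1 vector of true classes
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to compute a ROC curve")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels); nneg <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y); cum_fp <- cumsum(!y)
  last <- which(!duplicated(s, fromLast = TRUE))
  pts <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, cum_fp[last] / nneg),
                    tpr = c(0, cum_tp[last] / npos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Threshold nearest the (0, 1) ROC corner
#'
#' Returns the score threshold whose (FPR, TPR) point minimises the Euclidean
#' distance to the perfect-classification corner (0, 1); ties resolve to the
#' higher threshold. Constant scores give that constant with a warning.
#'
#' @param roc result of [roc_auc()], or its `points` data.frame
#' @return scalar threshold
#' @export
optimal_threshold <- function(roc) {
  pts <- if (is.data.frame(roc)) roc else roc$points
  pts <- pts[is.finite(pts$threshold), , drop = FALSE]
  if (nrow(pts) == 0L) stop("empty ROC")
  if (nrow(pts) == 1L) {
    warning("constant scores; threshold degenerate")
    return(pts$threshold[1])
  }
  d2 <- pts$fpr^2 + (1 - pts$tpr)^2
  best <- which(d2 == min(d2))
  max(pts$threshold[best])
}

#' Matthews correlation coefficient at a threshold
#'
#' Standard MCC of the 2x2 confusion table obtained by predicting positive
#' when score >= threshold; defined as 0 when any marginal is empty.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold
#' @return list with `mcc` and counts `tp`, `fp`, `tn`, `fn`
#' @export
mcc_at <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (denom == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  list(mcc = mcc, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Predicted positive fraction
#'
#' Share of residues called viable at a threshold: #{score >= threshold} / n.
#'
#' @inheritParams mcc_at
#' @return fraction in [0, 1]
#' @export
ppf <- function(scores, threshold) {
  mean(scores >= threshold)
}

#' Threshold fixing the predicted positive fraction
#'
#' Largest threshold whose PPF is at least the target; under score ties the
#' achieved fraction may overshoot the target and is reported alongside.
#'
#' @inheritParams roc_auc
#' @param target_ppf desired fraction in (0, 1)
#' @return list with `threshold` and `achieved_ppf`
#' @export
threshold_at_ppf <- function(scores, target_ppf) {
  stopifnot(target_ppf > 0, target_ppf < 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  fractions <- vapply(thr, function(t) mean(scores >= t), numeric(1))
  ok <- which(fractions >= target_ppf)
  t_star <- thr[ok[1]]
  list(threshold = t_star, achieved_ppf = fractions[ok[1]])
}

#' Retrieval table at fixed score cutoffs
#'
#' One row per cutoff with the predicted positive fraction, recall,
#' precision and retrieved counts, in the layout used to map prediction
#' reliability across probability-score levels. Precision with zero
#' retrieved residues is reported as 1 with the `empty` flag set.
#'
#' @inheritParams roc_auc
#' @param cutoffs decision thresholds, sorted descending
#' @return data.frame with `cutoff`, `ppf`, `recall`, `precision`,
#'   `n_true_retrieved`, `n_retrieved`, `empty`
#' @export
retrieval_table <- function(scores, labels,
                            cutoffs = c(0.80, 0.75, 0.70, 0.60, 0.50,
                                        0.40, 0.30, 0.20, 0.10, 0.00)) {
  labels <- as.logical(labels)
  stopifnot(!is.unsorted(rev(cutoffs)))
  rows <- lapply(cutoffs, function(ct) {
    pred <- scores >= ct
    n_ret <- sum(pred)
    n_true <- sum(pred & labels)
    data.frame(cutoff = ct,
               ppf = mean(pred),
               recall = if (sum(labels) == 0) NA_real_ else
                 n_true / sum(labels),
               precision = if (n_ret == 0) 1 else n_true / n_ret,
               n_true_retrieved = n_true,
               n_retrieved = n_ret,
               empty = n_ret == 0)
  })
  do.call(rbind, rows)
}

#' Seeded class-stratified cross-validation folds
#'
#' Partitions cases into k folds, stratifying on the class label so every
#' fold has a near-equal class balance. The folds partition the data exactly.
#'
#' @param labels logical or 0/1 class vector
#' @param k number of folds
#' @param seed RNG seed
#' @return integer fold id per case (1..k)
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.logical(labels)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Full binary evaluation report
#'
#' AUC, MCC, sensitivity, specificity, false positive rate, PPF and the
#' confusion counts at a decision threshold; when no threshold is given the
#' nearest-(0,1) ROC threshold is used.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold, or `NULL` to pick it from the ROC
#' @return object of class `cp_eval`
#' @export
evaluate_scores <- function(scores, labels, threshold = NULL) {
  labels <- as.logical(labels)
  roc <- roc_auc(scores, labels)
  if (is.null(threshold)) threshold <- optimal_threshold(roc)
  m <- mcc_at(scores, labels, threshold)
  sens <- if (m$tp + m$fn == 0) NA_real_ else m$tp / (m$tp + m$fn)
  spec <- if (m$tn + m$fp == 0) NA_real_ else m$tn / (m$tn + m$fp)
  structure(
    list(auc = roc$auc, mcc = m$mcc,
         sensitivity = sens, specificity = spec,
         false_positive_rate = if (is.na(spec)) NA_real_ else 1 - spec,
         decision_threshold = threshold,
         ppf = ppf(scores, threshold),
         counts = c(TP = m$tp, FP = m$fp, TN = m$tn, FN = m$fn),
         roc_points = roc$points),
    class = "cp_eval"
  )
}

#' @export
print.cp_eval <- function(x, ...) {
  cat(sprintf(
    paste0("CP viability evaluation\n",
           "  AUC %.3f  MCC %.3f  threshold %.4g\n",
           "  sensitivity %.3f  specificity %.3f  FPR %.3f  PPF %.3f\n",
           "  TP %d  FP %d  TN %d  FN %d\n"),
    x$auc, x$mcc, x$decision_threshold,
    x$sensitivity, x$specificity, x$false_positive_rate, x$ppf,
    x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  invisible(x)
}
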