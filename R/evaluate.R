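#' Confusion matrix with a fixed class order
#'
#' @param truth,pred vectors of true and predicted labels.
#' @param class_order the fixed ordered set of class labels.
#' @return An n x n integer matrix of class `confusion`, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(truth, pred, class_order = NULL) {
  if (is.null(class_order))
    class_order <- if (is.factor(truth)) levels(truth) else
      sort(unique(c(as.character(truth), as.character(pred))))
  t_f <- factor(as.character(truth), levels = class_order)
  p_f <- factor(as.character(pred), levels = class_order)
  cm <- unclass(table(truth = t_f, predicted = p_f))
  structure(cm, class = c("confusion", class(cm)))
}

as_counts <- function(c) {
  m <- unclass(c)
  storage.mode(m) <- "double"
  m
}

#' Cohen's kappa from a confusion matrix
#'
#' K = (Po - Pe) / (1 - Pe) with Po the observed agreement (trace/total) and
#' Pe the chance agreement sum_i row_i * col_i / total^2. In the degenerate
#' case Pe = 1 the statistic is undefined and 0 is returned with a warning.
#'
#' @param c a [confusion_matrix()] (or any square count matrix).
#' @return Kappa in [-1, 1].
#' @export
kappa_statistic <- function(c) {
  m <- as_counts(c)
  tot <- sum(m)
  if (tot < 1) stop("empty confusion matrix", call. = FALSE)
  po <- sum(diag(m)) / tot
  pe <- sum(rowSums(m) * colSums(m)) / tot^2
  if (1 - pe < 1e-15) {
    warning("chance agreement Pe = 1; kappa undefined, returning 0", call. = FALSE)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Balanced accuracy (mean per-class recall)
#'
#' Classes with no true instances contribute recall 0 with a warning, the
#' conservative reading when a small class vanishes from a test split.
#'
#' @param c a [confusion_matrix()].
#' @return Mean over classes of diagonal/row-sum.
#' @export
balanced_accuracy <- function(c) {
  m <- as_counts(c)
  rs <- rowSums(m)
  if (any(rs == 0))
    warning("class(es) with no true instances contribute recall 0: ",
            paste(rownames(m)[rs == 0], collapse = ", "), call. = FALSE)
  rec <- ifelse(rs > 0, diag(m) / rs, 0)
  mean(rec)
}

#' Macro-averaged recall
#' @param c a [confusion_matrix()].
#' @export
recall_macro <- function(c) balanced_accuracy(c)

#' Macro-averaged one-vs-rest specificity
#'
#' Per class: TN / (TN + FP) treating that class as positive; averaged over
#' classes.
#'
#' @param c a [confusion_matrix()].
#' @export
specificity_macro <- function(c) {
  m <- as_counts(c)
  tot <- sum(m)
  spec <- vapply(seq_len(nrow(m)), function(i) {
    fp <- sum(m[-i, i])
    tn <- tot - sum(m[i, ]) - fp
    if (tn + fp == 0) return(0)
    tn / (tn + fp)
  }, numeric(1))
  mean(spec)
}

#' Support-weighted F1 score
#'
#' Per-class one-vs-rest F1 (0 where precision + recall degenerates),
#' weighted by the class's share of true instances.
#'
#' @param truth,pred label vectors.
#' @param class_order optional fixed class order.
#' @export
f1_weighted <- function(truth, pred, class_order = NULL) {
  cm <- as_counts(confusion_matrix(truth, pred, class_order))
  support <- rowSums(cm)
  f1 <- vapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    prec_den <- sum(cm[, i]); rec_den <- sum(cm[i, ])
    if (prec_den == 0 || rec_den == 0) return(0)
    prec <- tp / prec_den; rec <- tp / rec_den
    if (prec + rec == 0) return(0)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  if (sum(support) == 0) stop("no true instances", call. = FALSE)
  sum(f1 * support) / sum(support)
}

binary_auc <- function(pos, scores) {
  # Mann-Whitney formulation with average ranks for ties
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Support-weighted one-vs-rest AUC
#'
#' Per class present in the truth, the ROC AUC of that class's probability
#' column against the one-vs-rest indicator; classes absent from the truth
#' are skipped with a warning and the support weights renormalized.
#'
#' @param truth label vector.
#' @param scores numeric matrix, samples x classes, with class names as
#'   column names.
#' @export
auc_weighted <- function(truth, scores) {
  truth <- as.character(truth)
  classes <- colnames(scores)
  if (is.null(classes)) stop("scores must have class column names", call. = FALSE)
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  absent <- classes[support == 0]
  if (length(absent))
    warning("class(es) absent from truth skipped in AUC: ",
            paste(absent, collapse = ", "), call. = FALSE)
  keep <- support > 0
  aucs <- vapply(which(keep), function(i)
    binary_auc(truth == classes[i], scores[, i]), numeric(1))
  sum(aucs * support[keep]) / sum(support[keep])
}

#' Composite model evaluation value (Evalue)
#'
#' Evalue = -100 * mean(kappa) * mean(BA) * ln(max(sd(kappa) * sd(BA), eps)),
#' with sample standard deviations (ddof = 1) over the repeats. High means
#' with low spread score highest; the eps clamp keeps degenerate zero-spread
#' runs finite.
#'
#' @param kappas,bas per-repeat Kappa and Balanced Accuracy values
#'   (length >= 2).
#' @param eps clamp on the SD product (default 1e-12).
#' @export
evalue <- function(kappas, bas, eps = 1e-12) {
  if (length(kappas) < 2L || length(bas) < 2L)
    stop("Evalue needs at least 2 repeats", call. = FALSE)
  -100 * mean(kappas) * mean(bas) * log(max(stats::sd(kappas) * stats::sd(bas), eps))
}

#' Full metric set for one test-set prediction
#'
#' @param truth true labels of the test samples.
#' @param pred predicted labels.
#' @param scores samples x classes probability matrix (for AUC); may be
#'   `NULL`, in which case `auc_weighted` is `NA`.
#' @param class_order fixed class order.
#' @return list of class `metric_set` with kappa, balanced_accuracy,
#'   f1_weighted, auc_weighted, recall_macro, specificity_macro.
#' @export
metric_set <- function(truth, pred, scores = NULL, class_order = NULL) {
  cm <- confusion_matrix(truth, pred, class_order)
  structure(list(
    kappa = kappa_statistic(cm),
    balanced_accuracy = balanced_accuracy(cm),
    f1_weighted = f1_weighted(truth, pred, class_order),
    auc_weighted = if (is.null(scores)) NA_real_ else auc_weighted(truth, scores),
    recall_macro = recall_macro(cm),
    specificity_macro = specificity_macro(cm),
    confusion = cm
  ), class = "metric_set")
}

#' Aggregate per-repeat metrics into means, SDs and the Evalue
#'
#' @param metrics list of [metric_set()] objects, one per repeat.
#' @return list of class `repeated_evaluation` with `per_repeat` (data
#'   frame), `mean`, `sd` (named vectors) and `evalue`.
#' @export
aggregate_repeats <- function(metrics) {
  keys <- c("kappa", "balanced_accuracy", "f1_weighted", "auc_weighted",
            "recall_macro", "specificity_macro")
  per <- as.data.frame(do.call(rbind, lapply(metrics, function(m)
    vapply(keys, function(k) m[[k]], numeric(1)))))
  per$repeat_index <- seq_len(nrow(per)) - 1L
  mu <- vapply(keys, function(k) mean(per[[k]]), numeric(1))
  sdv <- vapply(keys, function(k) stats::sd(per[[k]]), numeric(1))
  ev <- if (nrow(per) >= 2L) evalue(per$kappa, per$balanced_accuracy) else NA_real_
  structure(list(per_repeat = per, mean = mu, sd = sdv, evalue = ev),
            class = "repeated_evaluation")
}

#' @export
print.repeated_evaluation <- function(x, ...) {
  cat(sprintf("repeated_evaluation over %d repeats\n", nrow(x$per_repeat)))
  cat(sprintf("  kappa             %.4f +/- %.4f\n", x$mean["kappa"], x$sd["kappa"]))
  cat(sprintf("  balanced accuracy %.4f +/- %.4f\n",
              x$mean["balanced_accuracy"], x$sd["balanced_accuracy"]))
  cat(sprintf("  weighted F1       %.4f\n", x$mean["f1_weighted"]))
  cat(sprintf("  Evalue            %.3f\n", x$evalue))
  invisible(x)
}
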