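#' Build a confusion matrix
#'
#' Rows are ground truth, columns predictions: entry (i, j) counts the
#' samples of true class i predicted as class j.
#'
#' @param truth,pred equal-length label vectors.
#' @param classNames class label order; defaults to the sorted union of
#'   the observed labels. Every observed label must be listed.
#' @return A [ConfusionMatrix-class].
#' @examples
#' cm <- confusionMatrix(c("A", "A", "B"), c("A", "B", "B"))
#' counts(cm)
#' @export
confusionMatrix <- function(truth, pred, classNames = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) == 0L) stopf("empty label vectors")
  if (length(truth) != length(pred))
    stopf("truth and pred lengths differ (%d vs %d)",
          length(truth), length(pred))
  if (is.null(classNames)) classNames <- sort(unique(c(truth, pred)))
  unknown <- setdiff(unique(c(truth, pred)), classNames)
  if (length(unknown))
    stopf("labels not in classNames: %s", paste(unknown, collapse = ", "))
  tf <- factor(truth, levels = classNames)
  pf <- factor(pred, levels = classNames)
  m <- as.matrix(table(tf, pf))
  dimnames(m) <- list(classNames, classNames)
  names(dimnames(m)) <- NULL
  asConfusionMatrix(m)
}

#' Wrap a count matrix as a ConfusionMatrix
#'
#' @param m square non-negative integer matrix; row/column names become
#'   the class labels (defaults to `C1, C2, ...`).
#' @return A [ConfusionMatrix-class].
#' @export
asConfusionMatrix <- function(m) {
  m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("C", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  storage.mode(m) <- "double"
  new("ConfusionMatrix", counts = m)
}

#' Overall accuracy of a confusion matrix
#'
#' `100 * sum(diagonal) / sum(all entries)`, in percent.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return Accuracy percentage in `[0, 100]`.
#' @examples
#' m <- asConfusionMatrix(matrix(c(3944, 52, 186, 4191), 2, 2,
#'   dimnames = list(c("Malignant", "Benign"), c("Malignant", "Benign"))))
#' overallAccuracy(m)  # 97.158...
#' @export
overallAccuracy <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- counts(cm)
  100 * sum(diag(m)) / sum(m)
}

#' One-vs-rest metrics for a single class
#'
#' Reduces the n x n confusion matrix to the binary problem "class c vs
#' rest" (TP = N_cc, FN = rest of row c, FP = rest of column c, TN =
#' remainder) and reports, in percent:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive
#' prediction rate `TP/(TP+FP)` and negative prediction rate
#' `TN/(TN+FN)`. A zero denominator yields `NA` with the corresponding
#' name listed in the `undefined` attribute (never silently 0 or 100).
#'
#' @param cm a [ConfusionMatrix-class].
#' @param className the positive class.
#' @return Named numeric vector `c(sen, spe, ppr, npr)` (percent) with
#'   attributes `counts` (TP, FN, FP, TN) and `undefined`.
#' @export
perClassMetrics <- function(cm, className) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- counts(cm)
  if (!className %in% rownames(m))
    stopf("unknown class '%s'", className)
  tp <- m[className, className]
  fn <- sum(m[className, ]) - tp
  fp <- sum(m[, className]) - tp
  tn <- sum(m) - tp - fn - fp
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- c(sen = ratio(tp, tp + fn), spe = ratio(tn, tn + fp),
           ppr = ratio(tp, tp + fp), npr = ratio(tn, tn + fn))
  attr(out, "counts") <- c(TP = tp, FN = fn, FP = fp, TN = tn)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Full metric report for a confusion matrix
#'
#' @param cm a [ConfusionMatrix-class].
#' @return List: `accuracy` (percent), `perClass` (data.frame with one
#'   row per class: sen/spe/ppr/npr percentages and TP/FN/FP/TN counts),
#'   `confusion` (count matrix), `n` (total samples).
#' @export
metricReport <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  cls <- classNames(cm)
  rows <- lapply(cls, function(cn) {
    v <- perClassMetrics(cm, cn)
    k <- attr(v, "counts")
    data.frame(class = cn, sen = v[["sen"]], spe = v[["spe"]],
               ppr = v[["ppr"]], npr = v[["npr"]],
               TP = k[["TP"]], FN = k[["FN"]], FP = k[["FP"]], TN = k[["TN"]],
               stringsAsFactors = FALSE)
  })
  list(accuracy = overallAccuracy(cm),
       perClass = do.call(rbind, rows),
       confusion = counts(cm), n = sum(counts(cm)))
}

#' Write a metric report as JSON
#'
#' @param report result of [metricReport()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMetricsJSON <- function(report, path) {
  obj <- list(accuracy = report$accuracy,
              n = report$n,
              classes = rownames(report$confusion),
              confusion = unname(apply(report$confusion, 1, function(r)
                as.numeric(r), simplify = FALSE)),
              perClass = report$perClass)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' ROC curve and trapezoidal AUC for binary scores
#'
#' Sweeps the decision threshold over the unique score values (ties
#' grouped into single steps), accumulating the false and true positive
#' rates, and integrates the curve by the trapezoidal rule. The curve
#' runs from (0, 0) to (1, 1).
#'
#' @param truth binary labels: logical, 0/1, or a factor/character
#'   vector whose *second* sorted level is the positive class (pass
#'   `positive` to override).
#' @param scores numeric scores, larger = more positive.
#' @param positive the positive-class label (optional).
#' @return List of class `"ROCCurve"`: `fpr`, `tpr`, `thresholds`
#'   (decreasing; `Inf` first for the empty-positive corner), `auc`.
#' @examples
#' rocCurve(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3))$auc  # 0.75
#' @export
rocCurve <- function(truth, scores, positive = NULL) {
  if (length(truth) != length(scores)) stopf("truth/scores length mismatch")
  y <- binarizeTruth(truth, positive)
  nPos <- sum(y); nNeg <- sum(!y)
  if (nPos == 0L || nNeg == 0L)
    stopf("ROC requires both classes present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # group tied scores into one threshold step
  lastOfGroup <- c(ss[-1] != ss[-length(ss)], TRUE)
  tp <- cumsum(ys)[lastOfGroup]
  fp <- cumsum(!ys)[lastOfGroup]
  tpr <- c(0, tp / nPos)
  fpr <- c(0, fp / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, ss[lastOfGroup]), auc = auc),
            class = "ROCCurve")
}

binarizeTruth <- function(truth, positive = NULL) {
  if (is.logical(truth)) return(truth)
  if (is.numeric(truth) && all(truth %in% c(0, 1))) return(truth == 1)
  lv <- sort(unique(as.character(truth)))
  if (is.null(positive)) {
    if (length(lv) != 2L) stopf("truth must be binary (got %d levels)", length(lv))
    positive <- lv[2]
  }
  as.character(truth) == positive
}

#' Micro-averaged multiclass ROC
#'
#' One-hot binarizes the true labels, pools all (indicator, score) pairs
#' across the classes into a single binary problem, and computes one ROC
#' curve and AUC over the pooled pairs.
#'
#' @param truth multiclass labels.
#' @param proba matrix of class probabilities, columns aligned with
#'   `classNames`.
#' @param classNames class order of `proba`'s columns; defaults to its
#'   column names.
#' @return A `"ROCCurve"` list as in [rocCurve()].
#' @export
microAverageROC <- function(truth, proba, classNames = colnames(proba)) {
  proba <- as.matrix(proba)
  if (is.null(classNames)) stopf("classNames required when proba has no colnames")
  if (ncol(proba) != length(classNames))
    stopf("proba has %d columns but %d class names", ncol(proba),
          length(classNames))
  if (nrow(proba) != length(truth))
    stopf("proba rows (%d) must match truth length (%d)", nrow(proba),
          length(truth))
  onehot <- outer(as.character(truth), classNames, "==")
  rocCurve(as.vector(onehot), as.vector(proba))
}

#' Export ROC points to CSV
#'
#' @param roc a `"ROCCurve"` from [rocCurve()] or [microAverageROC()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeROCPoints <- function(roc, path) {
  utils::write.csv(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                              tpr = roc$tpr), path, row.names = FALSE)
  invisible(path)
}

#' Plot a ROC curve to PNG
#'
#' @param roc a `"ROCCurve"`.
#' @param path output PNG path.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
plotROC <- function(roc, path, main = sprintf("ROC (AUC = %.4f)", roc$auc)) {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  plot(roc$fpr, roc$tpr, type = "l", lwd = 2, col = "steelblue",
       xlab = "False positive rate", ylab = "True positive rate",
       main = main, xlim = c(0, 1), ylim = c(0, 1))
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(path)
}
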