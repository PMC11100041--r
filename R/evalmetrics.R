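# Evaluation metrics: confusion matrix, precision/recall/F1, rank-based AUC,
# full reports, and 5-fold cross-validation with metric-value averaging.

#' Two-class confusion matrix
#'
#' @param truth,pred equal-length 0/1 label vectors (1 = eCRS).
#' @return 2x2 integer matrix, rows = truth, columns = prediction, in class
#'   order (non-eCRS, eCRS).
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("confusion_matrix: length mismatch")
  stopifnot(all(truth %in% 0:1), all(pred %in% 0:1))
  m <- matrix(0L, 2L, 2L, dimnames = list(truth = LABEL_LEVELS,
                                          predicted = LABEL_LEVELS))
  for (i in 1:2) for (j in 1:2)
    m[i, j] <- sum(truth == i - 1L & pred == j - 1L)
  m
}

#' Precision, recall and F1 for the positive class (eCRS)
#'
#' Zero denominators yield a metric of 0 with a flag rather than NaN.
#'
#' @param mat a 2x2 confusion matrix (rows truth, columns prediction).
#' @return list with `precision`, `recall`, `f1` and `flags`.
#' @export
precision_recall_f1 <- function(mat) {
  tp <- mat[2, 2]; fp <- mat[1, 2]; fn <- mat[2, 1]
  flags <- character()
  precision <- if (tp + fp == 0) { flags <- c(flags, "no_positive_predictions"); 0 }
               else tp / (tp + fp)
  recall <- if (tp + fn == 0) { flags <- c(flags, "no_positive_truth"); 0 }
            else tp / (tp + fn)
  f1 <- if (precision + recall == 0) { flags <- c(flags, "undefined_f1"); 0 }
        else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1, flags = flags)
}

#' F1 from a printed precision/recall pair
#' @param precision,recall the two rates.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Equals the probability that a random positive outscores a random negative,
#' with ties credited 0.5; computed from average ranks in O(n log n).
#'
#' @param truth 0/1 labels (1 = positive / eCRS).
#' @param scores positive-class scores.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) for single-class input.
#' @export
roc_auc <- function(truth, scores) {
  stopifnot(length(truth) == length(scores))
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0 || nneg == 0) {
    warning("roc_auc: undefined for single-class input")
    return(NA_real_)
  }
  r <- rank(scores) # average ranks handle ties as half-credit
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' One row per distinct threshold (score cutoffs, predictions positive at
#' `score >= threshold`), suitable for writing as CSV.
#'
#' @param truth 0/1 labels.
#' @param scores positive-class scores.
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(truth, scores) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  do.call(rbind, lapply(th, function(t) {
    pp <- scores >= t
    data.frame(threshold = t,
               fpr = if (nneg) sum(pp & truth == 0) / nneg else 0,
               tpr = if (npos) sum(pp & truth == 1) / npos else 0)
  }))
}

#' Full metrics report from labels and scores
#'
#' @param truth 0/1 labels.
#' @param pred 0/1 predictions.
#' @param scores positive-class scores (for AUC); optional.
#' @return a `metrics_report`: accuracy, recall, precision, F1, AUC and the
#'   confusion matrix.
#' @export
metrics_report <- function(truth, pred, scores = NULL) {
  mat <- confusion_matrix(truth, pred)
  prf <- precision_recall_f1(mat)
  auc <- if (is.null(scores)) NA_real_ else
    suppressWarnings(roc_auc(truth, scores))
  structure(list(accuracy = sum(diag(mat)) / sum(mat), recall = prf$recall,
                 precision = prf$precision, f1 = prf$f1, auc = auc,
                 confusion = mat, n = sum(mat), flags = prf$flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | recall %.4f | precision %.4f | F1 %.4f | AUC %s (n = %d)\n",
    x$accuracy, x$recall, x$precision, x$f1,
    if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc), x$n))
  print(x$confusion)
  invisible(x)
}

#' Serialize a metrics report as JSON
#' @param report a `metrics_report`.
#' @param path output file; omit for the JSON string.
#' @export
metrics_report_json <- function(report, path = NULL) {
  obj <- list(accuracy = report$accuracy, recall = report$recall,
              precision = report$precision, f1 = report$f1, auc = report$auc,
              n = report$n,
              confusion = list(tn = report$confusion[1, 1], fp = report$confusion[1, 2],
                               fn = report$confusion[2, 1], tp = report$confusion[2, 2]))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Evaluate a model on a test set
#'
#' @param model a built model (or a `resmini_fit`, whose best-epoch weights
#'   and stored normalizer are used).
#' @param groups non-empty list of `view_group`s with images.
#' @param normalizer intensity normalizer (ignored for fits).
#' @return a `metrics_report`.
#' @export
evaluate <- function(model, groups, normalizer = NULL) {
  if (length(groups) == 0) stop("evaluate: empty test set")
  if (inherits(model, "resmini_fit")) {
    normalizer <- model$normalizer
    model <- best_model(model)
  }
  res <- model_predict(model, groups, normalizer)
  truth <- match(res$true_label, LABEL_LEVELS) - 1L
  pred <- match(res$pred_label, LABEL_LEVELS) - 1L
  metrics_report(truth, pred, res$score_eCRS)
}

#' 5-fold cross-validation with metric-value averaging
#'
#' The model is re-initialized per fold via `model_factory(fold_seed)`, trained
#' on the other folds and evaluated on the held-out fold; the averaged report
#' is the arithmetic mean of the fold metric values (confusion matrices are
#' summed).
#'
#' @param model_factory function(seed) returning a fresh built model.
#' @param groups list of `view_group`s with images.
#' @param split_cfg a [split_config()] (its `k` and `level` are used).
#' @param train_cfg a [train_config()].
#' @return list with `folds` (k `metrics_report`s) and `average`.
#' @export
cross_validate <- function(model_factory, groups, split_cfg = split_config(),
                           train_cfg = train_config()) {
  folds <- kfold(groups, split_cfg)
  k <- split_cfg$k
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    res <- tryCatch({
      model <- model_factory(split_cfg$seed + f)
      cfg <- train_cfg
      cfg$seed <- train_cfg$seed + f
      fit <- train_model(model, groups[folds != f], groups[folds == f], cfg)
      evaluate(fit, groups[folds == f])
    }, error = function(e)
      stop("cross_validate: fold ", f, " failed: ", conditionMessage(e)))
    reports[[f]] <- res
  }
  avg <- function(field) mean(vapply(reports, function(r) r[[field]], 0))
  average <- structure(list(
    accuracy = avg("accuracy"), recall = avg("recall"),
    precision = avg("precision"), f1 = avg("f1"), auc = avg("auc"),
    confusion = Reduce(`+`, lapply(reports, function(r) r$confusion)),
    n = sum(vapply(reports, function(r) r$n, 0)), flags = character()),
    class = "metrics_report")
  list(folds = reports, average = average)
}
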