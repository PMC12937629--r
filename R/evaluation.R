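#' Confusion matrix
#'
#' `K x K` integer counts with rows indexing the true class and columns the
#' predicted class.
#'
#' @param truth,pred 0-based integer labels of equal length.
#' @param k Number of classes.
#' @param class_names Optional class names for dimnames.
#' @return An integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(truth, pred, k, class_names = NULL) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length", call. = FALSE)
  if (length(truth) == 0L) stop("no records to evaluate", call. = FALSE)
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (any(truth < 0L | truth >= k) || any(pred < 0L | pred >= k))
    stop(sprintf("labels must lie in 0..%d", k - 1L), call. = FALSE)
  cm <- matrix(0L, k, k)
  for (i in seq_along(truth)) cm[truth[i] + 1L, pred[i] + 1L] <-
      cm[truth[i] + 1L, pred[i] + 1L] + 1L
  if (is.null(class_names)) class_names <- paste0("C", seq_len(k) - 1L)
  dimnames(cm) <- list(truth = class_names, predicted = class_names)
  class(cm) <- c("confusion_matrix", "matrix", "array")
  cm
}

#' Per-class precision, recall, F1 and support
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, F1 their
#' harmonic mean.  A zero denominator yields 0 with a warning.
#'
#' @param cm A [confusion()] matrix.
#' @return Data frame with one row per class: `class`, `precision`,
#'   `recall`, `f1`, `support`.
#' @export
per_class_prf <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning(sprintf("%s undefined for class(es) %s; reported as 0", what,
                      paste(rownames(cm)[bad], collapse = ", ")),
              call. = FALSE)
    ifelse(den == 0, 0, num / den)
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  data.frame(class = rownames(cm), precision = precision, recall = recall,
             f1 = f1, support = rowSums(cm), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Aggregate per-class F1 scores
#'
#' Macro-F1 is the unweighted mean of the per-class F1 values; weighted F1
#' weights each class by its support.
#'
#' @param f1 Per-class F1 values.
#' @param supports Per-class supports (record counts); only needed for the
#'   weighted mean.
#' @return List with `macro_f1` and (when supports are given) `weighted_f1`.
#' @export
aggregate_f1 <- function(f1, supports = NULL) {
  out <- list(macro_f1 = mean(f1))
  if (!is.null(supports))
    out$weighted_f1 <- sum(f1 * supports) / sum(supports)
  out
}

#' One-vs-rest ROC curves and AUC
#'
#' Per-class AUC is computed with the rank statistic (Mann-Whitney, ties
#' counted one half); the ROC curve enumerates thresholds along the sorted
#' scores.  The macro average is the unweighted mean over classes with at
#' least one positive and one negative (others are excluded with a
#' warning); the micro average pools the `(score, indicator)` pairs of all
#' classes into one binary problem.
#'
#' @param scores `N x K` matrix of class scores (e.g. softmax
#'   probabilities).
#' @param truth 0-based integer labels of length `N`.
#' @return List of class `roc_report`: `per_class` (data frame with `class`
#'   and `auc`), `curves` (list of `(fpr, tpr)` data frames), `macro_auc`,
#'   `micro_auc`.
#' @export
roc_auc <- function(scores, truth) {
  n <- nrow(scores); k <- ncol(scores)
  stopifnot(length(truth) == n)
  aucs <- rep(NA_real_, k)
  curves <- vector("list", k)
  for (c in seq_len(k)) {
    pos <- truth == (c - 1L)
    if (any(pos) && any(!pos)) {
      aucs[c] <- rank_auc(scores[, c], pos)
      curves[[c]] <- roc_points(scores[, c], pos)
    }
  }
  if (anyNA(aucs))
    warning(sprintf("AUC undefined for class(es) %s (no positives or no negatives)",
                    paste(which(is.na(aucs)) - 1L, collapse = ", ")),
            call. = FALSE)
  pooled_scores <- as.vector(scores)
  pooled_truth <- as.vector(vapply(seq_len(k),
                                   function(c) truth == (c - 1L),
                                   logical(n)))
  out <- list(
    per_class = data.frame(class = paste0("C", seq_len(k) - 1L), auc = aucs,
                           stringsAsFactors = FALSE),
    curves = curves,
    macro_auc = mean(aucs, na.rm = TRUE),
    micro_auc = rank_auc(pooled_scores, pooled_truth)
  )
  class(out) <- "roc_report"
  out
}

# Mann-Whitney AUC: (mean rank of positives - (npos+1)/2) / nneg,
# with midranks for ties.
rank_auc <- function(scores, pos) {
  r <- rank(scores, ties.method = "average")
  npos <- sum(pos); nneg <- sum(!pos)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# ROC polyline over decreasing score thresholds (ties collapsed).
roc_points <- function(scores, pos) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- c(s[-1] != s[-length(s)], TRUE) # keep final point of each tie run
  data.frame(fpr = c(0, fp[last] / sum(!pos)),
             tpr = c(0, tp[last] / sum(pos)))
}

#' Cross-validation aggregation
#'
#' Mean and sample standard deviation of each numeric column over the
#' per-fold rows.
#'
#' @param fold_metrics Data frame with one row per fold.
#' @return Data frame with columns `metric`, `mean`, `sd`.
#' @export
cv_aggregate <- function(fold_metrics) {
  num <- fold_metrics[vapply(fold_metrics, is.numeric, TRUE)]
  if (nrow(num) < 2L) stop("need at least two folds", call. = FALSE)
  data.frame(metric = names(num),
             mean = vapply(num, mean, 1),
             sd = vapply(num, stats::sd, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Accuracy-complexity trade-off score
#'
#' A configurable normalised score combining an accuracy ratio and a
#' parameter-count ratio against a reference model:
#' `weight * (acc / acc_ref) + (1 - weight) * (params_ref / params)`,
#' clipped to `[0, 1]`.  The combination rule and weight are recorded with
#' the result so reports are self-describing.
#'
#' @param accuracy,parameters Candidate model accuracy and parameter count.
#' @param ref_accuracy,ref_parameters Reference model values.
#' @param weight Weight of the accuracy term, in `[0, 1]`.
#' @return List with `score`, `weight` and `formula`.
#' @export
normalized_score <- function(accuracy, parameters, ref_accuracy,
                             ref_parameters, weight = 0.5) {
  stopifnot(parameters > 0, ref_parameters > 0, weight >= 0, weight <= 1)
  raw <- weight * (accuracy / ref_accuracy) +
    (1 - weight) * (ref_parameters / parameters)
  list(score = min(max(raw, 0), 1), weight = weight,
       formula = "w * acc/acc_ref + (1 - w) * params_ref/params, clipped to [0,1]")
}

#' Evaluate a model on a dataset
#'
#' One inference pass producing softmax probabilities, hard predictions
#' (argmax, ties to the lowest class index) and the full evaluation
#' report: confusion matrix, per-class precision/recall/F1/AUC, macro and
#' weighted aggregates, accuracy and top-1 error.
#'
#' @param model A `bone_cnn` model.
#' @param data Dataset list with `x` and `y` (see [load_split()]).
#' @param class_names Optional class names.
#' @return An `eval_report` list.
#' @export
evaluate_model <- function(model, data, class_names = NULL) {
  ev <- eval_pass(model, data, probs = TRUE)
  pred <- max.col(ev$probs, ties.method = "first") - 1L
  k <- model$config$num_classes
  cm <- confusion(data$y, pred, k, class_names)
  prf <- per_class_prf(cm)
  roc <- roc_auc(ev$probs, data$y)
  prf$auc <- roc$per_class$auc
  agg <- aggregate_f1(prf$f1, prf$support)
  accuracy <- sum(diag(cm)) / sum(cm)
  report <- list(
    accuracy = accuracy,
    top1_error = 1 - accuracy,
    mean_loss = ev$loss,
    per_class = prf,
    macro_f1 = agg$macro_f1,
    weighted_f1 = agg$weighted_f1,
    macro_auc = roc$macro_auc,
    micro_auc = roc$micro_auc,
    confusion = cm,
    roc = roc,
    n = length(data$y)
  )
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation on %d records:\n", x$n))
  cat(sprintf("  accuracy %.4f (top-1 error %.4f), loss %.4f\n",
              x$accuracy, x$top1_error, x$mean_loss))
  cat(sprintf("  macro-F1 %.4f, weighted-F1 %.4f, macro-AUC %.4f, micro-AUC %.4f\n",
              x$macro_f1, x$weighted_f1, x$macro_auc, x$micro_auc))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes `metrics.json` (the full report), `confusion.csv` (K x K counts
#' with header row and column) and one `roc_class<k>.csv` per class with
#' defined ROC curve.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if needed).
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- report[c("accuracy", "top1_error", "mean_loss", "macro_f1",
                 "weighted_f1", "macro_auc", "micro_auc", "n")]
  js$per_class <- report$per_class
  js$confusion <- unclass(report$confusion)
  jsonlite::write_json(js, file.path(dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", matrix = "rowmajor")
  cm <- as.data.frame(unclass(report$confusion))
  cm <- cbind(truth = rownames(report$confusion), cm)
  utils::write.csv(cm, file.path(dir, "confusion.csv"), row.names = FALSE)
  for (c in seq_along(report$roc$curves)) {
    if (!is.null(report$roc$curves[[c]]))
      utils::write.csv(report$roc$curves[[c]],
                       file.path(dir, sprintf("roc_class%d.csv", c - 1L)),
                       row.names = FALSE)
  }
  invisible(dir)
}
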