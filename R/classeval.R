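# Soft-margin SVM wrapper and binary evaluation: confusion matrix, accuracy,
# ROC/AUC with drowsy as the positive class.

#' Train the margin classifier
#'
#' Soft-margin support vector machine with an RBF kernel on the selected
#' feature columns. The kernel bandwidth default is `1 / (d * var)` where
#' `d` is the number of columns and `var` the overall variance of the
#' training matrix; the features are already on a common `[0, 1]` scale, so
#' no further standardisation is applied.
#'
#' @param x Numeric training matrix (rows = windows, columns = selected
#'   features).
#' @param y Binary labels (0/1), both classes present with at least 2
#'   samples each.
#' @param cost Soft-margin cost C (default 1).
#' @param gamma RBF bandwidth; default `1 / (ncol(x) * var(x))`.
#' @param kernel Kernel name passed to the SVM backend (default
#'   `"radial"`).
#' @return A `steer_classifier` wrapping the fitted SVM.
#' @export
train_classifier <- function(x, y, cost = 1, gamma = NULL,
                             kernel = "radial") {
  x <- as.matrix(x)
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("training requires at least 2 samples in each class",
         call. = FALSE)
  }
  if (is.null(gamma)) {
    v <- stats::var(as.numeric(x))
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = kernel,
                    cost = cost, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, gamma = gamma, cost = cost), class = "steer_classifier")
}

#' @rdname train_classifier
#' @param object A `steer_classifier`.
#' @param newdata Numeric matrix with the same columns as the training
#'   matrix.
#' @return `predict_labels`: integer 0/1 predictions; `decision_scores`:
#'   real-valued scores oriented so that larger means more drowsy.
#' @export
predict_labels <- function(object, newdata) {
  as.integer(as.character(stats::predict(object$fit, as.matrix(newdata))))
}

#' @rdname train_classifier
#' @export
decision_scores <- function(object, newdata) {
  pr <- stats::predict(object$fit, as.matrix(newdata),
                       decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm's decision value is positive for the class named first in the
  # column label "a/b"; orient so that positive favours the drowsy class 1
  lab <- strsplit(colnames(dv)[1], "/")[[1]]
  if (lab[1] == "1") as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
}

#' Confusion matrix with drowsy as the positive class
#'
#' @param pred Predicted labels (0/1).
#' @param truth True labels (0/1).
#' @return A `confusion_matrix`: list with counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_matrix <- function(pred, truth) {
  structure(list(tp = sum(pred == 1 & truth == 1),
                 tn = sum(pred == 0 & truth == 0),
                 fp = sum(pred == 1 & truth == 0),
                 fn = sum(pred == 0 & truth == 1)),
            class = "confusion_matrix")
}

#' Accuracy percentage from confusion counts
#'
#' `(TP + TN) / (TP + FP + TN + FN) * 100`.
#'
#' @param tp,tn,fp,fn Confusion counts, or a single `confusion_matrix` as
#'   `tp`.
#' @return Accuracy in percent.
#' @export
#' @examples
#' accuracy_from_counts(tp = 9515, tn = 24212, fp = 814, fn = 538)
accuracy_from_counts <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (inherits(tp, "confusion_matrix")) {
    cm <- tp
    tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  }
  (tp + tn) / (tp + fp + tn + fn) * 100
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps the decision threshold over the observed scores (prediction
#' positive when `score >= threshold`) and integrates the curve by the
#' trapezoid rule. Equals the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`.
#'
#' @param scores Real-valued scores, larger = more drowsy.
#' @param truth True labels (0/1), both classes present.
#' @return List with `roc` (data frame `fpr`, `tpr`, from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  check_two_classes(truth)
  np <- sum(truth == 1)
  nn <- sum(truth == 0)
  ord <- order(scores, decreasing = TRUE)
  tr <- truth[ord]
  sc <- scores[ord]
  tp <- cumsum(tr == 1)
  fp <- cumsum(tr == 0)
  # one ROC point per distinct score (last index of each tied block)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a classifier on a test set
#'
#' @param object A `steer_classifier`.
#' @param x Test feature matrix (selected columns).
#' @param y True labels (0/1).
#' @return An `eval_report`: list with `confusion` (counts), `accuracy`
#'   (percent, per [accuracy_from_counts()]), `roc` (data frame) and `auc`.
#' @export
evaluate_classifier <- function(object, x, y) {
  stopifnot(length(y) > 0)
  pred <- predict_labels(object, x)
  cm <- confusion_matrix(pred, y)
  rc <- if (length(unique(y)) == 2) {
    roc_curve(decision_scores(object, x), y)
  } else {
    list(roc = data.frame(fpr = numeric(0), tpr = numeric(0)), auc = NA_real_)
  }
  structure(list(confusion = cm, accuracy = accuracy_from_counts(cm),
                 roc = rc$roc, auc = rc$auc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cm <- x$confusion
  cat("Evaluation (drowsy = positive)\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", cm$tp, cm$fp, cm$tn, cm$fn))
  cat(sprintf("  accuracy %.3f%%", x$accuracy))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.4f", x$auc))
  cat("\n")
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(confusion = report$confusion[c("tp", "tn", "fp", "fn")],
              accuracy = report$accuracy, auc = report$auc,
              roc = list(fpr = report$roc$fpr, tpr = report$roc$tpr))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
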