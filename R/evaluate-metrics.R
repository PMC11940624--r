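#' ROC curve points
#'
#' Operating points at every unique threshold of the continuous score
#' (a case is called positive when its score is at or above the
#' threshold), anchored at (0,0) and (1,1). The trapezoidal AUC equals
#' the Mann-Whitney U statistic scaled by \eqn{1/(n_+ n_-)}, ties
#' counted one half.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector; both classes must be present.
#' @return data.frame (threshold, fpr, tpr) with attribute \code{auc}.
#' @export
roc_points <- function(scores, labels) {
  y <- as.integer(labels)
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present to build a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / npos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / nneg,
                numeric(1))
  out <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (out$fpr[nrow(out)] < 1 || out$tpr[nrow(out)] < 1)
    out <- rbind(out, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(out$fpr) * (out$tpr[-1] + out$tpr[-nrow(out)]) / 2)
  attr(out, "auc") <- auc
  out
}

#' Trapezoidal AUC
#'
#' @param scores,labels see [roc_points()].
#' @return scalar AUC.
#' @export
auc_score <- function(scores, labels) attr(roc_points(scores, labels), "auc")

#' Diagnostic metric panel from confusion counts
#'
#' The standard identities: sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), PPV TP/(TP+FP), NPV TN/(TN+FN), accuracy (TP+TN)/n with
#' an exact (Clopper-Pearson) binomial 95\% CI.
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @param conf_level CI level (default 0.95).
#' @return named list: counts, sensitivity, specificity, ppv, npv,
#'   accuracy, ci_lower, ci_upper.
#' @export
metric_panel <- function(tp, fp, tn, fn, conf_level = 0.95) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion matrix")
  ci <- stats::binom.test(tp + tn, n, conf.level = conf_level)$conf.int
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       accuracy = (tp + tn) / n,
       ci_lower = ci[1], ci_upper = ci[2])
}

#' Train a classifier and evaluate it on the held-out partition
#'
#' Fits the requested classifier on the training rows only, scores the
#' held-out test rows, and reports the full panel: AUC from the
#' continuous score, confusion counts at the classifier's decision
#' threshold (0.5 posterior, or 0 decision value for the SVM),
#' sensitivity/specificity/PPV/NPV, accuracy with exact binomial CI,
#' and permutation importance of every predictor on the 1-AUC scale.
#' A single-class test partition yields an NA AUC with the remaining
#' metrics still reported.
#'
#' @param kind classifier kind, see [fit_classifier()].
#' @param predictors matrix or data.frame of predictors (named cols).
#' @param labels 0/1 vector.
#' @param split list(train, test) from [split_cohort()].
#' @param seed integer seed (fit and importance permutations).
#' @param importance_reps permutation replicates (default 100).
#' @param ... classifier hyperparameters passed to [fit_classifier()].
#' @return a \code{classifier_report}: list with kind, metric panel
#'   fields, \code{auc}, \code{importance}, \code{roc}, \code{scores},
#'   \code{model}.
#' @export
train_and_evaluate <- function(kind, predictors, labels, split, seed = 1L,
                               importance_reps = 100L, ...) {
  X <- as.matrix(predictors)
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y))
  Xtr <- X[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xte <- X[split$test, , drop = FALSE]; yte <- y[split$test]
  model <- fit_classifier(kind, Xtr, ytr, seed = seed, ...)
  sc <- predict_score(model, Xte)
  pred <- as.integer(sc >= model$threshold)
  tp <- sum(pred == 1L & yte == 1L); fp <- sum(pred == 1L & yte == 0L)
  tn <- sum(pred == 0L & yte == 0L); fn <- sum(pred == 0L & yte == 1L)
  panel <- metric_panel(tp, fp, tn, fn)
  both <- length(unique(yte)) == 2L
  roc <- if (both) roc_points(sc, yte) else NULL
  auc <- if (both) attr(roc, "auc") else NA_real_
  imp <- if (both && ncol(X) >= 2L)
    importance_1auc(model, Xte, yte, reps = importance_reps,
                    seed = seed)
  else NULL
  structure(c(list(kind = kind, auc = auc, importance = imp, roc = roc,
                   scores = sc, labels_test = yte, model = model),
              panel),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report %s>\n  AUC %.3f | sens %.3f spec %.3f | PPV %.3f NPV %.3f | acc %.3f (%.3f to %.3f)\n",
    x$kind, x$auc, x$sensitivity, x$specificity, x$ppv, x$npv,
    x$accuracy, x$ci_lower, x$ci_upper))
  if (!is.null(x$importance)) {
    cat("  importance (1-AUC):",
        paste(sprintf("%s=%.3f", names(x$importance), x$importance),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Permutation importance on the 1-AUC scale
#'
#' Importance of predictor j = \eqn{1 - } mean AUC of the fitted
#' model's test scores after permuting predictor j, averaged over
#' \code{reps} seeded permutations. Permuting a non-influential
#' predictor leaves the AUC unchanged, so its importance equals
#' 1 - AUC of the intact model in expectation.
#'
#' @param model a fitted \code{us_classifier}.
#' @param X_test,y_test held-out predictors and labels (both classes).
#' @param reps permutation replicates (default 100).
#' @param seed integer seed.
#' @return named numeric vector, one importance per predictor.
#' @export
importance_1auc <- function(model, X_test, y_test, reps = 100L, seed = 1L) {
  X_test <- as.matrix(X_test)
  nms <- colnames(X_test)
  if (is.null(nms)) nms <- paste0("x", seq_len(ncol(X_test)))
  with_local_seed(seed, {
    vapply(seq_len(ncol(X_test)), function(j) {
      aucs <- vapply(seq_len(reps), function(r) {
        Xp <- X_test
        Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
        auc_score(predict_score(model, Xp), y_test)
      }, numeric(1))
      1 - mean(aucs)
    }, numeric(1)) -> imp
    stats::setNames(imp, nms)
  })
}
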