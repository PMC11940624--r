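#!/usr/bin/env Rscript
# Step 4: compute per-lesion Rad-Scores from the fitted models and
# evaluate the four classifiers (random forest, boosting, KNN, RBF-SVM)
# on {Rad-Score, Ki67 category} over a stratified 75/25 split. Writes
# one performance table per ROI scope (the Tables 4-5 layout: AUC,
# specificity, sensitivity, PPV, NPV, accuracy with exact 95% CI, and
# permutation importances on the 1-AUC scale) plus ROC point tables.

suppressPackageStartupMessages(library(usradiomics))

seed <- 1L
meta <- read.csv("results/cohort/cohort.csv", stringsAsFactors = FALSE)
kinds <- c("random_forest", "boosting", "knn", "svm")

eval_scope <- function(feat_path, model_path, tag) {
  tab <- read.csv(feat_path, check.names = FALSE)
  x <- as.matrix(tab[, -1])
  mj <- jsonlite::read_json(model_path, simplifyVector = TRUE)
  model <- radscore_model(unlist(mj$beta), lambda = mj$lambda,
                          scope = mj$scope, center = unlist(mj$center),
                          scale = unlist(mj$scale))
  rs <- rad_score(x, model)
  write.csv(data.frame(id = tab$id, rad_score = rs),
            sprintf("results/radscores_%s.csv", tag), row.names = FALSE)
  predictors <- cbind(rad_score = rs, ki67_high = meta$ki67_high)
  split <- split_cohort(meta$label, seed = seed)
  rows <- list()
  for (kind in kinds) {
    rep_ <- train_and_evaluate(kind, predictors, meta$label, split,
                               seed = seed)
    rows[[kind]] <- data.frame(
      classifier = kind, auc = rep_$auc, specificity = rep_$specificity,
      sensitivity = rep_$sensitivity, ppv = rep_$ppv, npv = rep_$npv,
      accuracy = rep_$accuracy, ci_lower = rep_$ci_lower,
      ci_upper = rep_$ci_upper,
      imp_rad_score = rep_$importance[["rad_score"]],
      imp_ki67 = rep_$importance[["ki67_high"]])
    write.csv(rep_$roc, sprintf("results/roc_%s_%s.csv", tag, kind),
              row.names = FALSE)
  }
  perf <- do.call(rbind, rows)
  write.csv(perf, sprintf("results/performance_%s.csv", tag),
            row.names = FALSE)
  cat(sprintf("\n== %s (test n = %d) ==\n", tag, length(split$test)))
  print(perf[, c("classifier", "auc", "sensitivity", "specificity",
                 "accuracy")], row.names = FALSE, digits = 3)
  invisible(perf)
}

eval_scope("results/features_tumor.csv",
           "results/selection_tumor_radscore_model.json", "radscore1")
eval_scope("results/features_peritumoral.csv",
           "results/selection_peritumoral_radscore_model.json", "radscore2")
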