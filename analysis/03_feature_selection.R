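#!/usr/bin/env Rscript
# Step 3: the three-step feature-selection cascade on the full cohort
# (Mann-Whitney + Benjamini-Hochberg at adjusted p < 0.050; Spearman
# pruning at |rho| > 0.9; LASSO logistic regression with stratified
# 10-fold CV, lambda at minimal mean binomial deviance), separately for
# the tumor-only and tumor+peritumoral tables. Writes the audit trails,
# the deviance-vs-lambda curves, and the Rad-Score models.

suppressPackageStartupMessages(library(usradiomics))

seed <- 1L
meta <- read.csv("results/cohort/cohort.csv", stringsAsFactors = FALSE)

run_one <- function(path, scope_tag, out_prefix) {
  tab <- read.csv(path, check.names = FALSE)
  x <- as.matrix(tab[, -1])
  rownames(x) <- tab$id
  sel <- run_cascade(x, meta$label, seed = seed, scope_tag = scope_tag)
  cat(sprintf("%s: %s\n", scope_tag,
              paste(sprintf("%s=%s", names(sel$counts), sel$counts),
                    collapse = " -> ")))
  if (length(sel$final))
    cat("  final features:", paste(sel$final, collapse = ", "), "\n")
  write.csv(sel$step1$audit, paste0(out_prefix, "_step1_audit.csv"),
            row.names = FALSE)
  write.csv(sel$step2$audit, paste0(out_prefix, "_step2_audit.csv"),
            row.names = FALSE)
  write.csv(sel$step3$cv, paste0(out_prefix, "_cv_deviance.csv"),
            row.names = FALSE)
  if (!is.null(sel$model)) {
    m <- sel$model
    jsonlite::write_json(
      list(scope = m$scope, lambda = m$lambda, beta = as.list(m$beta),
           center = as.list(m$center), scale = as.list(m$scale)),
      paste0(out_prefix, "_radscore_model.json"), auto_unbox = TRUE,
      digits = NA)
  }
  sel
}

sel1 <- run_one("results/features_tumor.csv", "radscore1",
                "results/selection_tumor")
sel2 <- run_one("results/features_peritumoral.csv", "radscore2",
                "results/selection_peritumoral")
cat(sprintf("chosen lambda: %.4g (tumor), %.4g (tumor+peritumoral)\n",
            sel1$step3$lambda, sel2$step3$lambda))
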