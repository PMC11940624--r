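#' Selection + Rad-Score + classifier evaluation on one feature table
#'
#' The modeling backbone applied to an extracted feature table: run the
#' three-step selection cascade (full-cohort scope by default, as the
#' protocol states), build the Rad-Score model from the LASSO
#' survivors, score every lesion, and evaluate the requested classifier
#' on \{Rad-Score, Ki67\} over a stratified 75/25 split.
#'
#' @param features numeric matrix, lesions x named features.
#' @param labels 0/1 vector (1 = P/LP-positive).
#' @param ki67_high 0/1 vector (Ki67 >= 20\%).
#' @param classifier classifier kind (default \code{"knn"}).
#' @param seed integer seed driving the CV folds, the split and the
#'   classifier fit.
#' @param alpha,threshold,k,rule cascade controls, see [run_cascade()].
#' @param split_ratio training fraction (default 0.75).
#' @param scope_tag Rad-Score scope label.
#' @param importance_reps permutation-importance replicates.
#' @return list: \code{selection} (\code{selection_result}),
#'   \code{model} (NULL if the cascade halted; the Rad-Score is then
#'   identically 0), \code{rad_scores}, \code{split}, \code{report}
#'   (\code{classifier_report}).
#' @export
evaluate_feature_table <- function(features, labels, ki67_high,
                                   classifier = "knn", seed = 1L,
                                   alpha = 0.050, threshold = 0.9,
                                   k = 10L, rule = "min",
                                   split_ratio = 0.75,
                                   scope_tag = "radscore1",
                                   importance_reps = 100L) {
  sel <- run_cascade(features, labels, alpha = alpha, threshold = threshold,
                     k = k, seed = seed, rule = rule, scope_tag = scope_tag)
  # a halted cascade (no informative feature) yields the empty linear
  # combination: Rad-Score 0 for every lesion, evaluated as-is
  rs <- if (is.null(sel$model)) rep(0, nrow(features))
        else rad_score(features, sel$model)
  predictors <- cbind(rad_score = rs, ki67_high = as.numeric(ki67_high))
  split <- split_cohort(labels, ratio = split_ratio, seed = seed)
  report <- train_and_evaluate(classifier, predictors, labels, split,
                               seed = seed,
                               importance_reps = importance_reps)
  list(selection = sel, model = sel$model, rad_scores = rs, split = split,
       report = report)
}

#' End-to-end synthetic pipeline run
#'
#' Simulates an image cohort, extracts the tumor and tumor+peritumoral
#' feature tables, and runs [evaluate_feature_table()] on the requested
#' ROI scope. This is the single-call version of the full analysis
#' chain used for validation: generator -> ROIs -> texture features ->
#' cascade -> Rad-Score -> classifier.
#'
#' @param config a [cohort_config()].
#' @param roi \code{"tumor"} or \code{"tumor_plus_peritumoral"}.
#' @param classifier classifier kind (default \code{"knn"}).
#' @param seed integer seed for selection/split/fit (the cohort's own
#'   seed lives in \code{config}).
#' @param margin_mm peritumoral margin in mm.
#' @param cfg a [norm_config()].
#' @param dmax,max_scale registry parameters.
#' @param ... further arguments to [evaluate_feature_table()].
#' @return as [evaluate_feature_table()], plus \code{features} and
#'   \code{meta}.
#' @export
run_synthetic_pipeline <- function(config = cohort_config(),
                                   roi = c("tumor",
                                           "tumor_plus_peritumoral"),
                                   classifier = "knn", seed = 1L,
                                   margin_mm = 7.5, cfg = norm_config(),
                                   dmax = 5L, max_scale = 6L, ...) {
  roi <- match.arg(roi)
  cohort <- simulate_cohort(config)
  feats <- extract_cohort_features(cohort, margin_mm = margin_mm, cfg = cfg,
                                   dmax = dmax, max_scale = max_scale)
  scope_tag <- if (roi == "tumor") "radscore1" else "radscore2"
  res <- evaluate_feature_table(feats[[roi]], feats$meta$label,
                                feats$meta$ki67_high,
                                classifier = classifier, seed = seed,
                                scope_tag = scope_tag, ...)
  res$features <- feats[[roi]]
  res$meta <- feats$meta
  res
}
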