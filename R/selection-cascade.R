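#' Step 1: univariate Mann-Whitney filter with FDR control
#'
#' Tests every feature for a location difference between the two groups
#' with [mann_whitney()], adjusts across features with [bh_adjust()],
#' and keeps exactly the features with adjusted p strictly below
#' \code{alpha}. Features containing undefined (NA) values are dropped
#' before testing, with the reason recorded; an empty survivor set is a
#' valid result.
#'
#' @param x numeric matrix, lesions x named features.
#' @param labels 0/1 vector (1 = positive class), length nrow(x).
#' @param alpha adjusted-p threshold (default 0.050).
#' @return list: \code{kept} (character), \code{audit} (data.frame:
#'   feature, U, p, p_adj, kept, reason).
#' @export
univariate_filter <- function(x, labels, alpha = 0.050) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (min(table(factor(labels, levels = c(0, 1)))) < 2)
    stop("need at least 2 samples per class")
  nm <- colnames(x)
  defined <- !apply(x, 2, anyNA)
  U <- p <- rep(NA_real_, ncol(x))
  for (j in which(defined)) {
    mw <- mann_whitney(x[labels == 1, j], x[labels == 0, j])
    U[j] <- mw$U; p[j] <- mw$p
  }
  p_adj <- rep(NA_real_, ncol(x))
  p_adj[defined] <- bh_adjust(p[defined])
  kept <- defined & !is.na(p_adj) & p_adj < alpha
  audit <- data.frame(
    feature = nm, U = U, p = p, p_adj = p_adj, kept = kept,
    reason = ifelse(!defined, "undefined values",
                    ifelse(kept, "", "adjusted p >= alpha")),
    stringsAsFactors = FALSE)
  list(kept = nm[kept], audit = audit)
}

#' Step 2: Spearman redundancy pruning
#'
#' Greedy removal of highly inter-correlated features: while any
#' retained pair has |Spearman rho| above the threshold, the pair with
#' the largest |rho| is located (ties broken by registry order) and its
#' member with the larger mean absolute correlation against all
#' currently retained features is dropped. Constant features, whose
#' correlation is undefined, are dropped first. The surviving set has
#' all pairwise |rho| at or below the threshold.
#'
#' @param x numeric matrix, lesions x named features (>= 3 rows).
#' @param threshold |rho| cutoff (default 0.9).
#' @return list: \code{kept} (character), \code{audit} (data.frame:
#'   feature, dropped, mean_abs_corr, reason).
#' @export
correlation_prune <- function(x, threshold = 0.9) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 3) stop("need at least 3 samples")
  nm <- colnames(x)
  if (ncol(x) == 0)
    return(list(kept = character(),
                audit = data.frame(feature = character(),
                                   dropped = logical(),
                                   mean_abs_corr = numeric(),
                                   reason = character())))
  constant <- apply(x, 2, function(v) length(unique(v)) == 1)
  drop_reason <- stats::setNames(rep("", ncol(x)), nm)
  drop_mac <- stats::setNames(rep(NA_real_, ncol(x)), nm)
  drop_reason[constant] <- "constant feature (undefined correlation)"
  keep <- which(!constant)
  if (length(keep) >= 2) {
    rho <- abs(stats::cor(x[, keep, drop = FALSE], method = "spearman"))
    diag(rho) <- 0
    while (length(keep) >= 2 && max(rho) > threshold) {
      top <- which(rho == max(rho), arr.ind = TRUE)
      # earliest pair in registry order
      top <- top[top[, 1] < top[, 2], , drop = FALSE]
      top <- top[order(top[, 1], top[, 2]), , drop = FALSE][1, ]
      mac <- rowMeans(rho) * length(keep) / (length(keep) - 1)
      i <- top[1]; j <- top[2]
      # drop the member with the larger mean absolute correlation;
      # on a tie drop the later one in registry order
      victim <- if (mac[i] > mac[j]) i else j
      vic_name <- colnames(rho)[victim]
      drop_reason[vic_name] <-
        sprintf("|rho| = %.3f with %s exceeds %.2f", max(rho),
                colnames(rho)[if (victim == i) j else i], threshold)
      drop_mac[vic_name] <- mac[victim]
      keep <- keep[keep != keep[victim]]
      rho <- rho[-victim, -victim, drop = FALSE]
    }
  }
  kept_names <- nm[sort(keep)]
  audit <- data.frame(
    feature = nm,
    dropped = !(nm %in% kept_names),
    mean_abs_corr = drop_mac,
    reason = drop_reason,
    stringsAsFactors = FALSE)
  list(kept = kept_names, audit = audit)
}

#' Step 3: LASSO-penalized logistic regression with cross-validation
#'
#' Standardizes the features (global zero mean, unit variance), fits
#' the penalized binomial model over glmnet's log-spaced lambda path
#' (from the data-derived lambda_max downward), scores each lambda by
#' mean binomial deviance over k stratified folds, and selects lambda
#' by minimal mean deviance (or the 1-SE rule). Coefficients are
#' reported on the standardized scale; survivors are the features with
#' nonzero coefficients at the chosen lambda.
#'
#' A single-feature input falls back to an unpenalized logistic fit
#' (lambda = 0), since a one-column design admits no selection problem.
#'
#' @param x numeric matrix, lesions x named features.
#' @param labels 0/1 vector.
#' @param k number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param rule \code{"min"} (default) or \code{"1se"}.
#' @return list: \code{beta} (named, standardized scale, nonzero and
#'   zero entries), \code{kept}, \code{lambda}, \code{cv} (data.frame:
#'   lambda, mean deviance, SE), \code{center}, \code{scale},
#'   \code{rule}.
#' @export
lasso_logistic_cv <- function(x, labels, k = 10L, seed = 1L,
                              rule = c("min", "1se")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  y <- as.integer(labels)
  if (nrow(x) < k) stop("fewer samples than folds")
  if (min(table(factor(y, levels = c(0, 1)))) < ceiling(k / 2))
    stop("a class is too small for ", k, "-fold stratified CV")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) stop("constant feature reached the LASSO step: ",
                          paste(colnames(x)[scl == 0], collapse = ", "))
  xs <- scale(x, center = ctr, scale = scl)

  if (ncol(x) == 1L) {
    fit <- stats::glm(y ~ xs, family = stats::binomial())
    beta <- stats::setNames(stats::coef(fit)[2], colnames(x))
    return(list(beta = beta, kept = colnames(x), lambda = 0,
                cv = data.frame(lambda = 0,
                                deviance = fit$deviance / length(y),
                                se = NA_real_),
                center = ctr, scale = scl, rule = rule))
  }

  foldid <- with_local_seed(seed, {
    f <- integer(length(y))
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  cvfit <- glmnet::cv.glmnet(xs, y, family = "binomial", foldid = foldid,
                             standardize = FALSE,
                             type.measure = "deviance")
  lam <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  b <- as.numeric(stats::coef(cvfit, s = lam))[-1] # drop intercept
  names(b) <- colnames(x)
  list(beta = b, kept = colnames(x)[b != 0], lambda = lam,
       cv = data.frame(lambda = cvfit$lambda, deviance = cvfit$cvm,
                       se = cvfit$cvsd),
       center = ctr, scale = scl, rule = rule)
}

#' Run the three-step feature-selection cascade
#'
#' Applies, in order and on the full cohort (the protocol's stated
#' selection scope; set \code{scope = "train_only"} with a train index
#' to obtain the leakage-free variant), the univariate Mann-Whitney /
#' Benjamini-Hochberg filter, Spearman redundancy pruning, and
#' LASSO-penalized logistic regression. The audit trail records every
#' feature's fate; survivor sets are nested by construction. An empty
#' intermediate set halts the cascade with an informative (empty)
#' result.
#'
#' @param x numeric matrix, lesions x named features.
#' @param labels 0/1 vector.
#' @param alpha step-1 adjusted-p threshold (default 0.050).
#' @param threshold step-2 |rho| cutoff (default 0.9).
#' @param k,seed,rule step-3 CV controls, see [lasso_logistic_cv()].
#' @param scope \code{"full_cohort"} (default) or \code{"train_only"}.
#' @param train_index row indices used when \code{scope = "train_only"}.
#' @param scope_tag label for the resulting Rad-Score model
#'   (\code{"radscore1"} tumor-only, \code{"radscore2"}
#'   tumor+peritumoral).
#' @return a \code{selection_result}: list with \code{counts} (named:
#'   input, step1, step2, step3), \code{step1}, \code{step2},
#'   \code{step3} audits, \code{final} (character), \code{model} (a
#'   \code{radscore_model} or NULL), \code{halted}.
#' @export
run_cascade <- function(x, labels, alpha = 0.050, threshold = 0.9,
                        k = 10L, seed = 1L, rule = "min",
                        scope = c("full_cohort", "train_only"),
                        train_index = NULL, scope_tag = "radscore1") {
  scope <- match.arg(scope)
  if (scope == "train_only") {
    if (is.null(train_index)) stop("`train_index` required for train_only scope")
    xs <- x[train_index, , drop = FALSE]; ys <- labels[train_index]
  } else {
    xs <- x; ys <- labels
  }
  counts <- c(input = ncol(x), step1 = NA_integer_, step2 = NA_integer_,
              step3 = NA_integer_)
  s1 <- univariate_filter(xs, ys, alpha)
  counts["step1"] <- length(s1$kept)
  if (length(s1$kept) == 0)
    return(structure(list(counts = counts, step1 = s1, step2 = NULL,
                          step3 = NULL, final = character(), model = NULL,
                          halted = "step1: no feature passed the FDR filter"),
                     class = "selection_result"))
  s2 <- correlation_prune(xs[, s1$kept, drop = FALSE], threshold)
  counts["step2"] <- length(s2$kept)
  if (length(s2$kept) == 0)
    return(structure(list(counts = counts, step1 = s1, step2 = s2,
                          step3 = NULL, final = character(), model = NULL,
                          halted = "step2: no feature survived pruning"),
                     class = "selection_result"))
  s3 <- lasso_logistic_cv(xs[, s2$kept, drop = FALSE], ys, k = k,
                          seed = seed, rule = rule)
  counts["step3"] <- length(s3$kept)
  model <- if (length(s3$kept) > 0)
    radscore_model(beta = s3$beta[s3$kept], lambda = s3$lambda,
                   scope = scope_tag,
                   center = s3$center[s3$kept], scale = s3$scale[s3$kept],
                   registry = colnames(x))
  else NULL
  structure(list(counts = counts, step1 = s1, step2 = s2, step3 = s3,
                 final = s3$kept, model = model, halted = NULL),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n  survivors:",
      paste(sprintf("%s=%s", names(x$counts), x$counts), collapse = " -> "),
      "\n")
  if (!is.null(x$halted)) cat("  halted:", x$halted, "\n")
  if (length(x$final)) cat("  final:", paste(x$final, collapse = ", "), "\n")
  invisible(x)
}
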