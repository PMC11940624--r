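#' Pearson chi-square test on a contingency table
#'
#' \eqn{\chi^2 = \sum (O - E)^2 / E} against the independence model,
#' WITHOUT continuity correction, df = (r-1)(c-1). This uncorrected
#' form reproduces, from the printed group counts, every categorical
#' p-value of the study's cohort-characteristics table (the
#' Yates-corrected variant does not).
#'
#' @param tab integer matrix (>= 2x2), categories x groups.
#' @return named list: \code{chi2}, \code{df}, \code{p}.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column marginal")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Compare group ages
#'
#' Group medians plus the two-sided Mann-Whitney p-value (the same
#' nonparametric test the feature filter uses).
#'
#' @param a,b numeric age vectors.
#' @return named list: \code{median_a}, \code{median_b}, \code{p}.
#' @export
compare_ages <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  mw <- mann_whitney(a, b)
  list(median_a = stats::median(a), median_b = stats::median(b), p = mw$p)
}

#' Per-feature batch-effect check between machines
#'
#' Welch two-sample t-test of every feature between the two acquisition
#' machines. The summary flag declares "no batch effect" iff the
#' smallest per-feature p exceeds 0.050 (the screening criterion used
#' before feature selection). Constant features have an undefined (NA)
#' p, flagged rather than silently dropped.
#'
#' @param x numeric matrix, lesions x named features.
#' @param machine character/factor vector of machine ids (2 levels).
#' @return list: \code{table} (data.frame: feature, t, p, defined),
#'   \code{no_batch_effect} (logical over defined features),
#'   \code{min_p}.
#' @export
batch_effect_test <- function(x, machine) {
  stopifnot(is.matrix(x), nrow(x) == length(machine))
  machine <- as.factor(machine)
  if (nlevels(machine) != 2) stop("exactly two machines are required")
  g1 <- machine == levels(machine)[1]
  tt <- rep(NA_real_, ncol(x)); pp <- rep(NA_real_, ncol(x))
  for (j in seq_len(ncol(x))) {
    a <- x[g1, j]; b <- x[!g1, j]
    if (anyNA(c(a, b)) || (stats::var(a) == 0 && stats::var(b) == 0)) next
    ht <- stats::t.test(a, b)
    tt[j] <- unname(ht$statistic); pp[j] <- ht$p.value
  }
  tab <- data.frame(feature = colnames(x), t = tt, p = pp,
                    defined = !is.na(pp), stringsAsFactors = FALSE)
  minp <- suppressWarnings(min(pp, na.rm = TRUE))
  list(table = tab,
       no_batch_effect = is.finite(minp) && minp > 0.050,
       min_p = if (is.finite(minp)) minp else NA_real_)
}

#' Group-comparison table of cohort characteristics
#'
#' The cohort-table layout: median age (with Mann-Whitney p) and, for
#' each categorical variable, per-group counts over its closed
#' vocabulary with the uncorrected Pearson chi-square p. Rows follow
#' the vocabulary order; empty levels are retained with zero counts.
#' P-values are also provided formatted to 3 decimals.
#'
#' @param cohort data.frame with columns \code{group} (two levels;
#'   "pathogenic" treated as positive if present), \code{age}, and any
#'   of \code{histology}, \code{grade}, \code{ki67}, \code{er},
#'   \code{pr}, \code{her2} (factors with their vocabulary as levels).
#' @return list: \code{age} (from [compare_ages()]), \code{categorical}
#'   (named list of list(counts, chi2, df, p, p_formatted)),
#'   \code{rows} (long-format data.frame mirroring the table layout).
#' @export
table2_report <- function(cohort) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  grp <- as.factor(cohort$group)
  if (nlevels(grp) != 2) stop("exactly two groups are required")
  pos <- if ("pathogenic" %in% levels(grp)) "pathogenic" else levels(grp)[1]
  neg <- setdiff(levels(grp), pos)
  out <- list()
  rows <- list()
  if ("age" %in% names(cohort)) {
    out$age <- compare_ages(cohort$age[grp == pos], cohort$age[grp == neg])
    rows[[length(rows) + 1]] <- data.frame(
      variable = "Age (median)", level = "",
      positive = out$age$median_a, negative = out$age$median_b,
      p = out$age$p, stringsAsFactors = FALSE)
  }
  cat_vars <- intersect(c("histology", "grade", "ki67", "er", "pr", "her2"),
                        names(cohort))
  out$categorical <- list()
  for (v in cat_vars) {
    f <- as.factor(cohort[[v]])
    counts <- table(f, grp)[, c(pos, neg), drop = FALSE]
    test <- pearson_chi2(counts)
    out$categorical[[v]] <- c(list(counts = counts), test,
                              list(p_formatted = sprintf("%.3f", test$p)))
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = rownames(counts),
      positive = as.numeric(counts[, 1]), negative = as.numeric(counts[, 2]),
      p = c(test$p, rep(NA_real_, nrow(counts) - 1)),
      stringsAsFactors = FALSE)
  }
  out$rows <- do.call(rbind, rows)
  out
}
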