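#' Stratified train/test split
#'
#' Splits the cohort 3:1 (75% training, 25% held-out test by default),
#' stratified by class so the class ratio is preserved within rounding.
#' Deterministic for a fixed seed; the two index sets are disjoint and
#' exhaustive.
#'
#' @param labels 0/1 vector.
#' @param ratio training fraction (default 0.75).
#' @param seed integer seed.
#' @return list: \code{train}, \code{test} (integer indices).
#' @export
split_cohort <- function(labels, ratio = 0.75, seed = 1L) {
  y <- as.integer(labels)
  if (any(table(factor(y, levels = c(0, 1))) < 4))
    stop("need at least 4 samples per class to stratify a ", ratio, " split")
  with_local_seed(seed, {
    train <- integer()
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      n_tr <- round(length(idx) * ratio)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}
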