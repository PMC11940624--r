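#' Tabular feature-set configuration
#'
#' Generates lesion x feature tables with known ground truth for
#' validating the selection cascade in isolation from the imaging
#' stack: \code{k} planted features carry a standardized mean shift
#' \eqn{\delta} between classes, optional equicorrelated blocks carry a
#' known within-block correlation, and everything else is exchangeable
#' standard normal noise.
#'
#' @param n_per_class samples per class (positive, negative); a single
#'   number is used for both.
#' @param n_features total feature count.
#' @param k number of planted (shifted) features, \code{k <= n_features}.
#' @param delta standardized mean shift of the planted features.
#' @param block_sizes integer vector of correlated-block sizes (placed
#'   after the planted features); may be empty.
#' @param rho_block within-block correlation, |rho| < 1.
#' @param seed integer seed.
#' @return a \code{feattab_config} list.
#' @export
feattab_config <- function(n_per_class = c(44L, 44L), n_features = 300L,
                           k = 5L, delta = 1.5, block_sizes = integer(),
                           rho_block = 0.95, seed = 1L) {
  if (length(n_per_class) == 1) n_per_class <- rep(n_per_class, 2)
  cfg <- list(n_per_class = as.integer(n_per_class),
              n_features = as.integer(n_features), k = as.integer(k),
              delta = delta, block_sizes = as.integer(block_sizes),
              rho_block = rho_block, seed = as.integer(seed))
  if (any(cfg$n_per_class < 1L)) stop("`n_per_class` must be >= 1")
  if (cfg$k > cfg$n_features) stop("`k` must be <= `n_features`")
  if (cfg$k + sum(cfg$block_sizes) > cfg$n_features)
    stop("planted features plus blocks exceed `n_features`")
  if (abs(cfg$rho_block) > 1) stop("|rho_block| must be <= 1")
  structure(cfg, class = "feattab_config")
}

#' Simulate a feature table with planted structure
#'
#' Columns are ordered: planted features \code{F001..F00k} (mean shift
#' \eqn{\delta} in the positive class, unit variance), then correlated
#' blocks \code{B<i>_<j>} (equicorrelated Gaussian, shared factor
#' construction, correlation \code{rho_block}; \code{rho_block = 1} is
#' honored exactly by duplicating one column), then pure-noise features
#' \code{N...}. Labels are 1 for the positive class.
#'
#' @param config a [feattab_config()].
#' @return list with \code{features} (matrix, named columns),
#'   \code{labels} (0/1 integer), \code{planted}, \code{blocks}
#'   (list of column-name vectors).
#' @export
simulate_feature_table <- function(config = feattab_config()) {
  stopifnot(inherits(config, "feattab_config"))
  n1 <- config$n_per_class[1]; n0 <- config$n_per_class[2]
  n <- n1 + n0; p <- config$n_features
  with_local_seed(config$seed, {
    labels <- rep(c(1L, 0L), c(n1, n0))
    x <- matrix(stats::rnorm(n * p), n, p)
    k <- config$k
    if (k > 0) x[labels == 1L, seq_len(k)] <- x[labels == 1L, seq_len(k)] +
        config$delta
    nm <- character(p)
    nm[seq_len(k)] <- sprintf("F%03d", seq_len(k))
    col <- k
    blocks <- list()
    rho <- config$rho_block
    for (b in seq_along(config$block_sizes)) {
      sz <- config$block_sizes[b]
      cols <- col + seq_len(sz)
      if (abs(rho) == 1) {
        base_col <- stats::rnorm(n)
        for (j in seq_len(sz)) x[, cols[j]] <- sign(rho)^(j - 1) * base_col
      } else {
        # shared-factor construction: corr(Xi, Xj) = rho for i != j
        z <- stats::rnorm(n)
        for (j in seq_len(sz))
          x[, cols[j]] <- sqrt(abs(rho)) * z +
            sqrt(1 - abs(rho)) * stats::rnorm(n)
      }
      nm[cols] <- sprintf("B%d_%d", b, seq_len(sz))
      blocks[[b]] <- nm[cols]
      col <- col + sz
    }
    if (col < p) nm[(col + 1):p] <- sprintf("N%03d", seq_len(p - col))
    colnames(x) <- nm
    rownames(x) <- sprintf("S%03d", seq_len(n))
    list(features = x, labels = labels,
         planted = nm[seq_len(k)], blocks = blocks)
  })
}
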