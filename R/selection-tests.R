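#' Mann-Whitney U test
#'
#' Rank-sum U statistic for two independent samples, with the
#' convention \eqn{U = R_a - n_a(n_a+1)/2} (number of pairs with a > b,
#' ties counted 1/2). Small samples (min group size <= 8, and at most
#' 1e5 group assignments) use exact enumeration of all assignments of
#' the pooled mid-ranks; otherwise the normal approximation with tie
#' correction and continuity correction is used. Two-sided p is the
#' doubled smaller tail, capped at 1.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exact_limit maximal number of enumerated assignments for the
#'   exact path (default 1e5).
#' @return named list: \code{U}, \code{p}, \code{method}.
#' @export
mann_whitney <- function(a, b, exact_limit = 1e5) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2

  n_assign <- choose(n, min(na, nb))
  if (min(na, nb) <= 8 && n_assign <= exact_limit) {
    # exact: every assignment of na of the pooled mid-ranks to group a
    idx <- utils::combn(n, na)
    Us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- na * nb / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The classical FDR-controlling step-up rule
#' \eqn{\tilde p_{(i)} = \min_{j \ge i} \min(1, m p_{(j)} / j)}:
#' order-preserving, idempotent, elementwise at least the raw p.
#' Delegates to \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0, 1] (NA passed through).
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
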