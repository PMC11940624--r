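#' First-order causal autoregressive texture model
#'
#' Fits, by least squares, the causal 2-D autoregression
#' \deqn{s(x, y) = \theta_1 s(x-1, y) + \theta_2 s(x-1, y-1) +
#'   \theta_3 s(x, y-1) + \theta_4 s(x+1, y-1) + e}
#' on mean-centered quantized levels, using every in-mask pixel whose
#' four causal neighbors (west, north-west, north, north-east) are also
#' in-mask. Here x indexes columns and y rows, so the neighbors are
#' left, upper-left, up, and upper-right. Sigma is the residual
#' standard deviation (the innovation spread).
#'
#' A rank-deficient design (e.g. a constant ROI) yields all theta = 0,
#' Sigma = 0 and the \code{degenerate} flag; fewer than 32 usable
#' pixels yields NA values with the \code{insufficient} flag.
#'
#' @param qroi a \code{quantized_roi}.
#' @return named numeric vector Teta1..Teta4, Sigma, with attribute
#'   \code{flag} in \{"ok", "degenerate", "insufficient"\}.
#' @export
ar_model <- function(qroi) {
  stopifnot(inherits(qroi, "quantized_roi"))
  L <- qroi$levels
  h <- nrow(L); w <- ncol(L)
  if (h < 3L || w < 3L)
    return(structure(c(Teta1 = NA_real_, Teta2 = NA_real_, Teta3 = NA_real_,
                       Teta4 = NA_real_, Sigma = NA_real_),
                     flag = "insufficient"))
  s <- L - mean(L, na.rm = TRUE)
  r <- 2:(h - 1); c2 <- 2:(w - 1)
  ctr <- s[r, c2, drop = FALSE]
  west <- s[r, c2 - 1, drop = FALSE]       # s(x-1, y)
  nw <- s[r - 1, c2 - 1, drop = FALSE]     # s(x-1, y-1)
  north <- s[r - 1, c2, drop = FALSE]      # s(x, y-1)
  ne <- s[r - 1, c2 + 1, drop = FALSE]     # s(x+1, y-1)
  ok <- !is.na(ctr) & !is.na(west) & !is.na(nw) & !is.na(north) & !is.na(ne)
  n <- sum(ok)
  if (n < 32L)
    return(structure(c(Teta1 = NA_real_, Teta2 = NA_real_, Teta3 = NA_real_,
                       Teta4 = NA_real_, Sigma = NA_real_),
                     flag = "insufficient"))
  X <- cbind(west[ok], nw[ok], north[ok], ne[ok])
  y <- ctr[ok]
  qrX <- qr(X)
  if (qrX$rank < 4L) {
    theta <- c(0, 0, 0, 0)
    sigma <- if (all(y == 0)) 0 else stats::sd(y)
    flag <- "degenerate"
    warning("rank-deficient AR design: theta set to 0")
  } else {
    theta <- qr.coef(qrX, y)
    sigma <- stats::sd(y - X %*% theta)
    flag <- "ok"
  }
  structure(c(Teta1 = theta[1], Teta2 = theta[2], Teta3 = theta[3],
              Teta4 = theta[4], Sigma = sigma),
            flag = flag)
}
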