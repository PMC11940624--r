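#' Gray-level co-occurrence matrix
#'
#' Counts pairs of quantized levels at a fixed pixel offset (dy, dx),
#' requiring both pixels of a pair to lie inside the mask, accumulates
#' symmetrically (each pair and its reverse), and normalizes to sum 1.
#'
#' @param qroi a \code{quantized_roi}.
#' @param dy,dx integer offset in pixels (rows, cols), not both zero.
#' @return an Ng x Ng \code{glc_matrix} (attributes: offset, symmetric),
#'   or NULL when no valid pair lies inside the mask.
#' @export
glcm <- function(qroi, dy, dx) {
  stopifnot(inherits(qroi, "quantized_roi"))
  dy <- as.integer(dy); dx <- as.integer(dx)
  if (dy == 0L && dx == 0L) stop("offset (0,0) is not a valid GLCM offset")
  L <- qroi$levels
  h <- nrow(L); w <- ncol(L); ng <- qroi$n_gray
  if (abs(dy) >= h || abs(dx) >= w) return(NULL)
  r0 <- max(1L, 1L - dy):min(h, h - dy)
  c0 <- max(1L, 1L - dx):min(w, w - dx)
  a <- L[r0, c0, drop = FALSE]
  b <- L[r0 + dy, c0 + dx, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  ai <- a[ok]; bi <- b[ok]
  counts <- tabulate(ai * ng + bi + 1L, nbins = ng * ng) +
    tabulate(bi * ng + ai + 1L, nbins = ng * ng)
  m <- matrix(counts / sum(counts), ng, ng, byrow = TRUE)
  structure(m, offset = c(dy, dx), symmetric = TRUE, class = "glc_matrix")
}

#' Haralick statistics of a co-occurrence matrix
#'
#' The eleven classical Haralick descriptors, with gray levels indexed
#' 1..Ng for the moment-type statistics, natural logarithms for the
#' entropies, and the convention 0 log 0 = 0. The sum-variance
#' statistic is centered on the sum average. A degenerate matrix with a
#' single nonzero entry yields AngScMom 1, Contrast 0 and zero
#' entropies; Correlation is set to 0 when either marginal variance
#' vanishes.
#'
#' @param m a \code{glc_matrix} (or any normalized Ng x Ng matrix).
#' @return named numeric vector: AngScMom, Contrast, Correlation,
#'   SumOfSqs, InvDfMom, SumAverg, SumVarnc, SumEntrp, Entropy,
#'   DifVarnc, DifEntrp.
#' @export
glcm_features <- function(m) {
  ng <- nrow(m)
  p <- as.numeric(m) # column-major: index = (j-1)*ng + i
  i <- rep(seq_len(ng), ng)        # row level of entry
  j <- rep(seq_len(ng), each = ng) # col level of entry

  xlog <- function(x) ifelse(x > 0, log(x), 0)

  px <- rowSums(m); py <- colSums(m)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))

  # distributions of i + j (2..2Ng) and |i - j| (0..Ng-1)
  psum <- as.numeric(rowsum(p, i + j))                 # ordered by unique sums
  sum_vals <- sort(unique(i + j))
  pdif <- as.numeric(rowsum(p, abs(i - j)))
  dif_vals <- sort(unique(abs(i - j)))

  sum_averg <- sum(sum_vals * psum)
  dif_mu <- sum(dif_vals * pdif)

  c(
    AngScMom = sum(p^2),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sdx * sdy > 0)
      (sum(i * j * p) - mux * muy) / (sdx * sdy) else 0,
    SumOfSqs = sum((i - mux)^2 * p),
    InvDfMom = sum(p / (1 + (i - j)^2)),
    SumAverg = sum_averg,
    SumVarnc = sum((sum_vals - sum_averg)^2 * psum),
    SumEntrp = -sum(psum * xlog(psum)),
    Entropy = -sum(p * xlog(p)),
    DifVarnc = sum((dif_vals - dif_mu)^2 * pdif),
    DifEntrp = -sum(pdif * xlog(pdif))
  )
}

# the (dy, dx) offsets of the feature registry: for d = 1..5 the four
# directions 0, 90, 45, 135 degrees at displacement d
glcm_offsets <- function(dmax = 5L) {
  out <- list()
  for (d in seq_len(dmax))
    out <- c(out, list(c(0L, d), c(d, 0L), c(d, d), c(d, -d)))
  out
}

glcm_offset_name <- function(off) sprintf("S(%d,%d)", off[1], off[2])
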