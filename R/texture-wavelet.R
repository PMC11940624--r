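#' Haar wavelet sub-band energies
#'
#' Orthonormal 2-D Haar multiresolution analysis of the ROI's
#' bounding-box patch, out-of-mask pixels filled with the in-mask mean
#' level. At each scale the current approximation is split into four
#' sub-bands via 2x2 orthonormal Haar blocks ("valid positions" only: a
#' trailing odd row/column is dropped, no periodization), and
#' \code{WavEn<band>_s<k>} is the mean squared band coefficient at
#' scale k over positions whose 2^k x 2^k support intersects the mask.
#' Band labels give horizontal then vertical frequency content: HL is
#' high-horizontal / low-vertical (responds to vertical edges).
#'
#' Scales whose input is smaller than 2 in either dimension (i.e. the
#' ROI bounding box is smaller than 2^k) yield NA for that scale's four
#' features.
#'
#' @param qroi a \code{quantized_roi}.
#' @param max_scale deepest decomposition scale (default 6).
#' @return named numeric vector WavEnLL_s1 .. WavEnHH_s<max_scale>,
#'   ordered scale-major (LL, LH, HL, HH within each scale).
#' @export
wavelet_energies <- function(qroi, max_scale = 6L) {
  stopifnot(inherits(qroi, "quantized_roi"))
  max_scale <- as.integer(max_scale)
  if (max_scale < 1L) stop("`max_scale` must be >= 1")
  L <- qroi$levels
  inmask <- !is.na(L)
  rr <- range(which(rowSums(inmask) > 0))
  cc <- range(which(colSums(inmask) > 0))
  patch <- L[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  msk <- inmask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  fill <- mean(L, na.rm = TRUE)
  patch[!msk] <- fill
  patch <- patch * 1.0

  bands <- c("LL", "LH", "HL", "HH")
  out <- stats::setNames(
    rep(NA_real_, 4L * max_scale),
    as.vector(vapply(seq_len(max_scale),
                     function(k) paste0("WavEn", bands, "_s", k),
                     character(4))))
  approx <- patch; m <- msk
  for (k in seq_len(max_scale)) {
    h <- nrow(approx); w <- ncol(approx)
    if (h < 2L || w < 2L) break
    h2 <- h %/% 2L; w2 <- w %/% 2L
    or <- seq_len(h2) * 2L - 1L; oc <- seq_len(w2) * 2L - 1L
    p11 <- approx[or, oc, drop = FALSE]
    p12 <- approx[or, oc + 1L, drop = FALSE]
    p21 <- approx[or + 1L, oc, drop = FALSE]
    p22 <- approx[or + 1L, oc + 1L, drop = FALSE]
    ll <- (p11 + p12 + p21 + p22) / 2
    hl <- (p11 - p12 + p21 - p22) / 2  # high horizontal frequency
    lh <- (p11 + p12 - p21 - p22) / 2  # high vertical frequency
    hh <- (p11 - p12 - p21 + p22) / 2
    # a scale-k position touches the mask if any pixel of its support does
    mk <- m[or, oc, drop = FALSE] | m[or, oc + 1L, drop = FALSE] |
      m[or + 1L, oc, drop = FALSE] | m[or + 1L, oc + 1L, drop = FALSE]
    if (any(mk)) {
      out[paste0("WavEnLL_s", k)] <- mean(ll[mk]^2)
      out[paste0("WavEnLH_s", k)] <- mean(lh[mk]^2)
      out[paste0("WavEnHL_s", k)] <- mean(hl[mk]^2)
      out[paste0("WavEnHH_s", k)] <- mean(hh[mk]^2)
    }
    approx <- ll; m <- mk
  }
  out
}
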