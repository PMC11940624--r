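#' Denoising stand-in: square median filter
#'
#' The source workflow denoised images with an unversioned commercial
#' tool; this package substitutes a documented, reproducible stand-in --
#' a median filter over a (2r+1) x (2r+1) window -- and keeps it OFF by
#' default so that fidelity experiments can bypass it entirely. Border
#' pixels use the truncated window (only in-image neighbors).
#'
#' @param img a \code{gray_image}.
#' @param enabled logical; FALSE (default) returns the image unchanged.
#' @param radius window radius in pixels (default 1, i.e. 3x3).
#' @return a \code{gray_image} of the same shape and spacing.
#' @export
preprocess <- function(img, enabled = FALSE, radius = 1L) {
  stopifnot(inherits(img, "gray_image"))
  if (!enabled) return(img)
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be >= 1")
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  # stack all window shifts; NA-pad outside the image, median ignores NA
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  stack <- array(NA_real_, dim = c(h, w, nrow(offs)))
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    src_r <- seq_len(h) + dy; src_c <- seq_len(w) + dx
    ok_r <- src_r >= 1 & src_r <= h; ok_c <- src_c >= 1 & src_c <= w
    sl <- array(NA_real_, dim = c(h, w))
    sl[ok_r, ok_c] <- px[src_r[ok_r], src_c[ok_c]]
    stack[, , k] <- sl
  }
  out <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
  gray_image(out, spacing_mm = img$spacing_mm, bit_depth = img$bit_depth)
}
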