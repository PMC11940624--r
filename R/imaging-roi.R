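#' Build the tumor + peritumoral ROI
#'
#' Dilates the tumor mask by a Euclidean disk whose radius is the
#' peritumoral margin converted to pixels (\code{round(margin_mm /
#' spacing_mm)}), subtracts the exclusion mask (skin, pectoral muscle),
#' and clips to the image frame. The margin must lie in the 0.5--1 cm
#' band the protocol defines for the peritumoral ring; the default is
#' its midpoint, 7.5 mm.
#'
#' The dilation is exact: a background pixel joins the ROI iff its
#' Euclidean distance to the nearest tumor pixel is at most the disk
#' radius (the nearest tumor pixel to any outside point is a tumor
#' boundary pixel, so only boundary pixels are scanned).
#'
#' @param tumor \code{roi_mask} with role \code{"tumor"}.
#' @param spacing_mm pixel spacing in mm/pixel.
#' @param margin_mm peritumoral margin in mm, in [5, 10]; default 7.5.
#' @param exclusion optional \code{roi_mask} with role \code{"exclusion"}.
#' @return a \code{roi_mask} with role \code{"tumor_plus_peritumoral"}.
#' @export
build_peritumoral <- function(tumor, spacing_mm, margin_mm = 7.5,
                              exclusion = NULL) {
  stopifnot(inherits(tumor, "roi_mask"))
  if (!any(tumor$mask)) stop("tumor mask is empty")
  if (margin_mm < 5 || margin_mm > 10)
    stop("`margin_mm` must lie in [5, 10] mm: the peritumoral ring is ",
         "defined as 0.5 to 1 cm of tissue surrounding the tumor")
  r <- round(margin_mm / spacing_mm)
  if (r < 1)
    stop("dilation radius rounds to ", r, " px: pixel spacing ", spacing_mm,
         " mm/px is too coarse for a ", margin_mm, " mm margin")
  m <- tumor$mask
  h <- nrow(m); w <- ncol(m)

  # tumor boundary: tumor pixels with a 4-neighbor outside the tumor or
  # on the image edge
  idx <- which(m, arr.ind = TRUE)
  bnd <- idx[is_boundary(m, idx), , drop = FALSE]

  # candidate pixels: non-tumor pixels within the bounding box padded by r
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  rows <- max(1, rr[1] - r):min(h, rr[2] + r)
  cols <- max(1, cc[1] - r):min(w, cc[2] + r)
  cand <- as.matrix(expand.grid(row = rows, col = cols))
  cand <- cand[!m[cand], , drop = FALSE]

  out <- m
  if (nrow(cand) > 0 && nrow(bnd) > 0) {
    # squared distance from every candidate to its nearest boundary pixel
    nn <- FNN::get.knnx(data = bnd, query = cand, k = 1)
    keep <- nn$nn.dist[, 1] <= r + 1e-9
    out[cand[keep, , drop = FALSE]] <- TRUE
  }
  if (!is.null(exclusion)) {
    stopifnot(inherits(exclusion, "roi_mask"))
    if (!identical(dim(exclusion$mask), dim(m)))
      stop("exclusion mask shape does not match tumor mask")
    out <- out & !exclusion$mask
  }
  roi_mask(out, role = "tumor_plus_peritumoral")
}

# TRUE for the rows of `idx` (arr.ind into m) that touch a non-mask
# 4-neighbor or the image edge
is_boundary <- function(m, idx) {
  h <- nrow(m); w <- ncol(m)
  r <- idx[, 1]; c <- idx[, 2]
  at_edge <- r == 1 | r == h | c == 1 | c == w
  nb <- function(dr, dc) {
    rr <- pmin(pmax(r + dr, 1), h); cc <- pmin(pmax(c + dc, 1), w)
    !m[cbind(rr, cc)]
  }
  at_edge | nb(-1, 0) | nb(1, 0) | nb(0, -1) | nb(0, 1)
}
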