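#' Normalization / quantization configuration
#'
#' Controls how in-ROI intensities are normalized and binned into gray
#' levels before texture analysis. The default, \code{mu3sigma} with
#' \code{n_gray = 64}, is the classical Mazda convention for
#' co-occurrence analysis: intensities are clamped to
#' \eqn{[\mu - 3\sigma, \mu + 3\sigma]} (moments over in-mask pixels)
#' and binned linearly, which makes every downstream feature exactly
#' invariant under positive affine transforms of the input intensities.
#' Normalization statistics are computed per ROI.
#'
#' @param mode \code{"mu3sigma"}, \code{"minmax"} or \code{"none"}.
#' @param n_gray number of gray levels Ng, a power of two >= 4.
#' @return a \code{norm_config} list.
#' @export
norm_config <- function(mode = c("mu3sigma", "minmax", "none"),
                        n_gray = 64L) {
  mode <- match.arg(mode)
  n_gray <- as.integer(n_gray)
  if (n_gray < 4L || bitwAnd(n_gray, n_gray - 1L) != 0L)
    stop("`n_gray` must be a power of two >= 4")
  structure(list(mode = mode, n_gray = n_gray), class = "norm_config")
}

#' Normalize and quantize an ROI
#'
#' Produces the integer-level substrate every texture family is computed
#' on: in-mask pixels carry a level in \code{0..Ng-1}, out-of-mask
#' pixels are NA. A constant ROI (\eqn{\sigma = 0} under
#' \code{mu3sigma}, or zero range under \code{minmax}) maps every pixel
#' to level 0 and sets the \code{constant} warning flag.
#'
#' The object also retains the continuous normalized intensities
#' (clamped, rescaled to the \code{[0, Ng-1]} axis, unbinned) which the
#' first-order histogram features are computed on; under
#' \code{mode = "none"} those are the raw intensities.
#'
#' @param img a \code{gray_image}.
#' @param mask a \code{roi_mask} (any role; must be non-empty).
#' @param cfg a [norm_config()].
#' @return a \code{quantized_roi}: list with \code{levels} (matrix,
#'   NA outside mask), \code{values} (continuous normalized in-mask
#'   intensities, mask order), \code{n_gray}, \code{role},
#'   \code{constant} flag, \code{spacing_mm}.
#' @export
normalize_quantize <- function(img, mask, cfg = norm_config()) {
  stopifnot(inherits(img, "gray_image"), inherits(mask, "roi_mask"),
            inherits(cfg, "norm_config"))
  check_mask_alignment(mask, img)
  if (!any(mask$mask)) stop("mask is empty")
  v <- img$pixels[mask$mask]
  ng <- cfg$n_gray
  constant <- FALSE
  if (cfg$mode == "mu3sigma") {
    mu <- mean(v); sig <- stats::sd(v)
    if (sig == 0) {
      constant <- TRUE
      warning("constant ROI: sigma = 0, all pixels assigned level 0")
      lev_in <- rep(0L, length(v)); val_in <- rep(0, length(v))
    } else {
      lo <- mu - 3 * sig; hi <- mu + 3 * sig
      cl <- pmin(pmax(v, lo), hi)
      val_in <- (cl - lo) / (hi - lo) * (ng - 1)
      lev_in <- pmin(as.integer(floor((cl - lo) / (hi - lo) * ng)), ng - 1L)
    }
  } else if (cfg$mode == "minmax") {
    lo <- min(v); hi <- max(v)
    if (hi == lo) {
      constant <- TRUE
      warning("constant ROI: zero range, all pixels assigned level 0")
      lev_in <- rep(0L, length(v)); val_in <- rep(0, length(v))
    } else {
      val_in <- (v - lo) / (hi - lo) * (ng - 1)
      lev_in <- pmin(as.integer(floor((v - lo) / (hi - lo) * ng)), ng - 1L)
    }
  } else { # none: bin the native intensity axis of the image bit depth
    maxv <- 2^img$bit_depth - 1
    val_in <- v
    lev_in <- pmin(as.integer(floor(v / (maxv + 1) * ng)), ng - 1L)
    if (length(unique(v)) == 1L) constant <- TRUE
  }
  levels <- array(NA_integer_, dim(img$pixels))
  levels[mask$mask] <- lev_in
  structure(
    list(levels = levels, values = val_in, n_gray = ng, role = mask$role,
         constant = constant, spacing_mm = img$spacing_mm),
    class = "quantized_roi"
  )
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi %s, %d px, Ng = %d%s>\n", x$role,
              sum(!is.na(x$levels)), x$n_gray,
              if (x$constant) ", constant" else ""))
  invisible(x)
}
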