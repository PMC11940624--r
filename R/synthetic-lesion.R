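#' Parameters of a synthetic ultrasound lesion
#'
#' Describes one speckle-textured hypoechoic mass on a brighter tissue
#' background, the stand-in for a segmented B-mode breast lesion. The
#' image model is deliberately minimal: a piecewise-constant
#' echogenicity map (lesion vs background) multiplied by Rayleigh
#' speckle, then Gaussian-smoothed with a correlation length that acts
#' as the single class-dependent texture knob.
#'
#' @param image_size_px integer (h, w).
#' @param pixel_spacing_mm isotropic spacing, mm/pixel.
#' @param lesion_center_px numeric (row, col) center.
#' @param lesion_radii_px numeric (semi-axis rows, semi-axis cols), > 0.
#' @param margin_irregularity radial perturbation amplitude as a
#'   fraction of the radius, in [0, 1); 0 gives an exact ellipse.
#' @param echogenicity_contrast lesion/background mean intensity ratio;
#'   < 1 gives the hypoechoic appearance typical of malignant masses.
#' @param speckle_scale Rayleigh scale of the multiplicative speckle
#'   (> 0); 0 is accepted as the exact noise-free limit.
#' @param texture_correlation_length_px Gaussian smoothing length (px)
#'   applied to the speckle field; larger values give coarser texture.
#' @param posterior_shadow logical; darken a band below the lesion.
#' @return a \code{lesion_params} list.
#' @export
lesion_params <- function(image_size_px = c(128L, 128L),
                          pixel_spacing_mm = 0.35,
                          lesion_center_px = image_size_px / 2,
                          lesion_radii_px = c(17, 14),
                          margin_irregularity = 0.15,
                          echogenicity_contrast = 0.45,
                          speckle_scale = 0.35,
                          texture_correlation_length_px = 1.5,
                          posterior_shadow = FALSE) {
  p <- list(image_size_px = as.integer(image_size_px),
            pixel_spacing_mm = pixel_spacing_mm,
            lesion_center_px = as.numeric(lesion_center_px),
            lesion_radii_px = as.numeric(lesion_radii_px),
            margin_irregularity = margin_irregularity,
            echogenicity_contrast = echogenicity_contrast,
            speckle_scale = speckle_scale,
            texture_correlation_length_px = texture_correlation_length_px,
            posterior_shadow = isTRUE(posterior_shadow))
  if (length(p$image_size_px) != 2 || any(p$image_size_px < 8))
    stop("`image_size_px` must be (h, w), both >= 8")
  if (p$pixel_spacing_mm <= 0) stop("`pixel_spacing_mm` must be > 0")
  if (any(p$lesion_radii_px <= 0)) stop("`lesion_radii_px` must be > 0")
  if (p$margin_irregularity < 0 || p$margin_irregularity >= 1)
    stop("`margin_irregularity` must lie in [0, 1)")
  if (p$speckle_scale < 0) stop("`speckle_scale` must be >= 0")
  if (p$texture_correlation_length_px < 0)
    stop("`texture_correlation_length_px` must be >= 0")
  # the perturbed lesion must fit fully inside the frame
  reach <- p$lesion_radii_px * (1 + p$margin_irregularity)
  if (p$lesion_center_px[1] - reach[1] < 1 ||
      p$lesion_center_px[1] + reach[1] > p$image_size_px[1] ||
      p$lesion_center_px[2] - reach[2] < 1 ||
      p$lesion_center_px[2] + reach[2] > p$image_size_px[2])
    stop("lesion (radii ", paste(signif(reach, 3), collapse = ", "),
         " px including margin irregularity) does not fit inside the ",
         paste(p$image_size_px, collapse = "x"), " image")
  structure(p, class = "lesion_params")
}

#' Simulate one speckle-textured lesion image
#'
#' Renders the echogenicity map of a (possibly margin-perturbed)
#' elliptical hypoechoic lesion, multiplies it by Rayleigh speckle,
#' smooths with a Gaussian kernel of the requested correlation length,
#' and maps to 8-bit. The tumor mask is exactly the perturbed-ellipse
#' interior; the exclusion mask is a thin top band emulating skin.
#' Fully deterministic for a fixed seed.
#'
#' The margin perturbation modulates the ellipse radius with a smooth
#' random Fourier series in polar angle, giving the microlobulated,
#' indistinct margins typical of suspicious masses.
#'
#' @param params a [lesion_params()].
#' @param seed integer seed.
#' @return list with \code{image} (\code{gray_image}), \code{tumor} and
#'   \code{exclusion} (\code{roi_mask}).
#' @export
simulate_lesion_image <- function(params = lesion_params(), seed = 1L) {
  stopifnot(inherits(params, "lesion_params"))
  h <- params$image_size_px[1]; w <- params$image_size_px[2]
  cy <- params$lesion_center_px[1]; cx <- params$lesion_center_px[2]
  ry <- params$lesion_radii_px[1]; rx <- params$lesion_radii_px[2]

  with_local_seed(seed, {
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    u <- (yy - cy) / ry; v <- (xx - cx) / rx
    rho <- sqrt(u^2 + v^2)

    # smooth radial margin perturbation: low-order random Fourier series
    if (params$margin_irregularity > 0) {
      theta <- atan2(u, v)
      nharm <- 5L
      amp <- stats::rnorm(nharm); phs <- stats::runif(nharm, 0, 2 * pi)
      pert <- rep(0, length(theta))
      for (k in seq_len(nharm))
        pert <- pert + amp[k] * cos((k + 1) * theta + phs[k])
      pert <- pert / max(abs(pert)) * params$margin_irregularity
      inside <- rho <= 1 + pert
    } else {
      inside <- rho <= 1
    }
    inside <- array(inside, c(h, w))

    # piecewise-constant echogenicity, background mean 1
    echo <- array(1, c(h, w))
    echo[inside] <- params$echogenicity_contrast
    if (params$posterior_shadow) {
      below <- yy > cy + ry & abs(v) <= 1
      echo[below] <- echo[below] * 0.55
    }

    # multiplicative Rayleigh speckle, unit mean, then Gaussian smoothing
    if (params$speckle_scale > 0) {
      ray <- params$speckle_scale * sqrt(-2 * log(stats::runif(h * w)))
      ray <- ray / (params$speckle_scale * sqrt(pi / 2)) # unit mean
      field <- echo * array(ray, c(h, w))
      field <- gaussian_blur(field, params$texture_correlation_length_px)
    } else {
      field <- echo
    }

    px <- pmin(pmax(round(field / max(field) * 220), 0), 255)
    img <- gray_image(px, spacing_mm = params$pixel_spacing_mm,
                      bit_depth = 8L)
    excl <- array(FALSE, c(h, w))
    excl[seq_len(max(2L, round(0.05 * h))), ] <- TRUE # skin band
    list(image = img,
         tumor = roi_mask(inside, "tumor"),
         exclusion = roi_mask(excl, "exclusion"))
  })
}

# separable Gaussian blur with reflected borders; sigma in px
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  blur1 <- function(mat) { # along rows (dim 1)
    n <- nrow(mat)
    idx <- outer(seq_len(n), -r:r, "+")
    idx <- abs(idx - 1) %% (2 * (n - 1)); idx <- pmin(idx, 2 * (n - 1) - idx) + 1
    out <- 0
    for (j in seq_along(k)) out <- out + k[j] * mat[idx[, j], , drop = FALSE]
    out
  }
  t(blur1(t(blur1(m))))
}
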