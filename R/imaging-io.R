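#' Grayscale ultrasound image
#'
#' A 2-D non-negative intensity raster with isotropic pixel spacing, the
#' unit every ROI and texture feature is computed on. Only grayscale
#' images are supported; color inputs are rejected because the analysis
#' is defined on B-mode grayscale data.
#'
#' @param pixels numeric matrix (rows = image rows), non-negative.
#' @param spacing_mm isotropic pixel spacing in mm/pixel (> 0).
#' @param bit_depth integer, 8 or 16; the nominal intensity range is
#'   \code{[0, 2^bit_depth - 1]}.
#' @return an object of class \code{gray_image}.
#' @export
gray_image <- function(pixels, spacing_mm, bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (anyNA(pixels) || any(pixels < 0))
    stop("image intensities must be non-negative and finite")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 || spacing_mm <= 0)
    stop("`spacing_mm` must be a single positive number (isotropic spacing; ",
         "anisotropic inputs are rejected rather than silently resampled)")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  structure(
    list(pixels = pixels, spacing_mm = as.numeric(spacing_mm),
         bit_depth = as.integer(bit_depth)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d-bit, %.4g mm/px>\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$spacing_mm))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' A logical raster aligned to a \code{gray_image}. The role records what
#' the mask delineates: the tumor core, the tumor plus its peritumoral
#' ring, or an exclusion zone (skin, pectoral muscle) subtracted from the
#' analyzed region.
#'
#' @param mask logical matrix (or 0/1 numeric, coerced).
#' @param role one of \code{"tumor"}, \code{"tumor_plus_peritumoral"},
#'   \code{"exclusion"}.
#' @return an object of class \code{roi_mask}.
#' @export
roi_mask <- function(mask, role = c("tumor", "tumor_plus_peritumoral",
                                    "exclusion")) {
  role <- match.arg(role)
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("numeric mask must be 0/1")
    mask <- array(mask > 0, dim(mask))
  }
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  if (anyNA(mask)) stop("mask must not contain NA")
  structure(list(mask = mask, role = role), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %s, %d x %d, %d px set>\n", x$role,
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

check_mask_alignment <- function(mask, image) {
  if (!identical(dim(mask$mask), dim(image$pixels)))
    stop("mask shape (", paste(dim(mask$mask), collapse = "x"),
         ") does not match image shape (",
         paste(dim(image$pixels), collapse = "x"), ")")
  invisible(TRUE)
}

#' Read a grayscale PNG image
#'
#' Reads an 8- or 16-bit grayscale PNG into a \code{gray_image} with
#' integer intensities on the native scale (0..255 or 0..65535). Color
#' images are rejected: the analysis is defined on grayscale data only.
#' TIFF is not supported in this build (no TIFF reader available); use
#' PNG.
#'
#' @param path path to a PNG file.
#' @param spacing_mm pixel spacing in mm/pixel (PNG carries no spacing).
#' @return a \code{gray_image}.
#' @export
load_image <- function(path, spacing_mm) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!grepl("\\.png$", path, ignore.case = TRUE))
    stop("unsupported format (PNG only): ", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) {
    # tolerate gray+alpha; reject true color
    if (dim(arr)[3] == 2) {
      arr <- arr[, , 1]
    } else {
      ch <- dim(arr)[3]
      rng <- max(abs(arr[, , 1] - arr[, , 2])) + max(abs(arr[, , 1] - arr[, , 3]))
      if (rng > 0) stop("color image: only grayscale images are analyzed")
      arr <- arr[, , 1]
    }
  }
  # readPNG scales to [0,1] by 2^depth-1; recover the integer scale
  depth <- if (any(abs(arr * 255 - round(arr * 255)) > 1e-9)) 16L else 8L
  px <- round(arr * (2^depth - 1))
  gray_image(px, spacing_mm = spacing_mm, bit_depth = depth)
}

#' Write a grayscale image as PNG
#'
#' Lossless for integer intensities within the image's bit depth:
#' \code{load_image(write_image(img))} reproduces the pixel values
#' exactly.
#'
#' @param img a \code{gray_image}.
#' @param path output path (.png).
#' @return \code{path}, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  maxv <- 2^img$bit_depth - 1
  if (any(img$pixels > maxv))
    stop("intensities exceed the image bit depth")
  if (img$bit_depth == 8L) {
    png::writePNG(img$pixels / maxv, target = path)
  } else {
    # png::writePNG stores 8-bit only; encode 16-bit grayscale directly
    write_png_gray16(round(img$pixels), path)
  }
  invisible(path)
}

# minimal 16-bit grayscale PNG encoder (color type 0, no interlace):
# filter-0 scanlines, zlib-deflated IDAT, CRC-32 per chunk
write_png_gray16 <- function(px, path) {
  h <- nrow(px); w <- ncol(px)
  be <- function(x, n) as.raw(x %/% 256^((n - 1):0) %% 256)
  v <- as.integer(t(px)) # row-major sample order
  rowdat <- matrix(as.raw(rbind(v %/% 256L, v %% 256L)), nrow = 2L * w)
  scan <- as.raw(rbind(rep(as.raw(0), h), matrix(rowdat, nrow = 2L * w)))
  idat <- memCompress(as.raw(scan), type = "gzip") # zlib stream
  ihdr <- c(be(w, 4), be(h, 4), as.raw(c(16, 0, 0, 0, 0)))
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(be(length(data), 4), body, be(png_crc32(body), 4))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(chunk("IHDR", ihdr), con)
  writeBin(chunk("IDAT", idat), con)
  writeBin(chunk("IEND", raw(0)), con)
  invisible(path)
}

png_crc32 <- local({
  tab <- NULL
  function(bytes) {
    if (is.null(tab)) {
      poly <- -306674912L # 0xEDB88320 as signed 32-bit
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8)
          c <- if (bitwAnd(c, 1L)) bitwXor(poly, bitwShiftR(c, 1))
               else bitwShiftR(c, 1)
        t[n + 1] <- c
      }
      tab <<- t
    }
    crc <- -1L # 0xFFFFFFFF
    for (b in as.integer(bytes))
      crc <- bitwXor(bitwShiftR(crc, 8),
                     tab[bitwAnd(bitwXor(crc, b), 255L) + 1])
    crc <- bitwXor(crc, -1L)
    if (crc < 0) crc + 2^32 else as.numeric(crc)
  }
})

#' Read a binary ROI mask from PNG
#'
#' The mask is binarized at half of the intensity range (the 0/255
#' convention: background 0, foreground 255). Shape must match the image.
#'
#' @param path path to a PNG mask.
#' @param image the \code{gray_image} the mask annotates.
#' @param role mask role, see [roi_mask()].
#' @return a \code{roi_mask}.
#' @export
load_mask <- function(path, image, role = "tumor") {
  if (!file.exists(path)) stop("no such file: ", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  m <- roi_mask(array(arr >= 0.5, dim(arr)), role = role)
  check_mask_alignment(m, image)
  m
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask a \code{roi_mask}.
#' @param path output path (.png).
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  png::writePNG(array(as.numeric(mask$mask), dim(mask$mask)), target = path)
  invisible(path)
}
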