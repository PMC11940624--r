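#' Gray-level runs along a direction
#'
#' Enumerates the maximal constant-level runs of an ROI along one of
#' the four principal directions. A run breaks at mask boundaries:
#' out-of-mask pixels split a scanline into independent segments.
#' Directions follow the Mazda labels: 0 (horizontal, along rows), 90
#' (vertical), 45 (anti-diagonal, up-right), 135 (diagonal, down-right).
#'
#' @param qroi a \code{quantized_roi}.
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @return data.frame with one row per run: \code{level},
#'   \code{length}; attribute \code{n_pixels} = in-mask pixels
#'   traversed.
#' @export
gray_level_runs <- function(qroi, angle) {
  stopifnot(inherits(qroi, "quantized_roi"))
  if (!angle %in% c(0, 45, 90, 135)) stop("angle must be 0, 45, 90 or 135")
  L <- qroi$levels
  h <- nrow(L); w <- ncol(L)
  rix <- matrix(seq_len(h), h, w)
  cix <- matrix(seq_len(w), h, w, byrow = TRUE)
  # scanline id; within a scanline, matrix element order must follow the
  # traversal direction
  if (angle == 0) {            # along a row: id = row, order by col
    id <- rix; ord <- order(id, cix)
  } else if (angle == 90) {    # along a column
    id <- cix; ord <- order(id, rix)
  } else if (angle == 45) {    # up-right: row + col constant
    id <- rix + cix; ord <- order(id, cix)
  } else {                     # 135, down-right: row - col constant
    id <- rix - cix; ord <- order(id, cix)
  }
  v <- as.integer(L)[ord]
  idv <- as.integer(id)[ord]
  # break runs at scanline changes by offsetting levels per scanline is
  # unsafe; instead splice a separator between scanlines
  brk <- c(TRUE, diff(idv) != 0L)
  v[is.na(v)] <- -1L
  # force a break by making the first element of each scanline unique?
  # simpler: run rle on (scanline, value) pairs encoded jointly
  enc <- as.numeric(idv) * (qroi$n_gray + 2) + v # distinct across scanlines
  r <- rle(enc)
  lev <- v[cumsum(r$lengths)]
  keep <- lev >= 0L
  runs <- data.frame(level = lev[keep], length = r$lengths[keep])
  attr(runs, "n_pixels") <- sum(runs$length)
  runs
}

#' Run-length features for one direction
#'
#' Classical Galloway/Mazda statistics of the run-length distribution:
#' short-run emphasis, long-run emphasis, gray-level non-uniformity,
#' run-length non-uniformity, and the run fraction (runs per traversed
#' in-mask pixel).
#'
#' @param qroi a \code{quantized_roi}.
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @return named numeric vector: ShrtREmp, LngREmph, GLevNonU,
#'   RLNonUni, Fraction.
#' @export
glrlm_features <- function(qroi, angle) {
  runs <- gray_level_runs(qroi, angle)
  n <- nrow(runs)
  if (n == 0L)
    return(c(RLNonUni = NA_real_, GLevNonU = NA_real_, ShrtREmp = NA_real_,
             LngREmph = NA_real_, Fraction = NA_real_))
  npix <- attr(runs, "n_pixels")
  per_level <- table(runs$level)
  per_length <- table(runs$length)
  c(
    RLNonUni = sum(as.numeric(per_length)^2) / n,
    GLevNonU = sum(as.numeric(per_level)^2) / n,
    ShrtREmp = sum(1 / runs$length^2) / n,
    LngREmph = sum(runs$length^2) / n,
    Fraction = n / npix
  )
}

glrlm_angle_prefixes <- c(`0` = "Horzl_", `45` = "45dgr_", `90` = "Vertl_",
                          `135` = "135dr_")
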