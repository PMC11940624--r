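#' First-order histogram features
#'
#' Moments and percentiles of the normalized in-ROI intensity
#' distribution (the continuous normalized values carried by the
#' \code{quantized_roi}; under \code{norm_config(mode = "none")} these
#' are the raw intensities). Moments are population moments; kurtosis
#' is excess kurtosis. Percentile p is the nearest-rank
#' \code{ceiling(p * n)}-th order statistic. A constant ROI has
#' variance 0 and undefined (NA) skewness and kurtosis.
#'
#' @param qroi a \code{quantized_roi}.
#' @return named numeric vector: Mean, Variance, Skewness, Kurtosis,
#'   Perc.01., Perc.10., Perc.50., Perc.90., Perc.99.
#' @export
histogram_features <- function(qroi) {
  stopifnot(inherits(qroi, "quantized_roi"))
  v <- qroi$values
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  if (m2 > 0) {
    skew <- mean((v - mu)^3) / m2^1.5
    kurt <- mean((v - mu)^4) / m2^2 - 3
  } else {
    skew <- NA_real_; kurt <- NA_real_
  }
  s <- sort(v)
  nr <- function(p) s[max(1L, ceiling(p * n))]
  c(Mean = mu, Variance = m2, Skewness = skew, Kurtosis = kurt,
    Perc.01. = nr(0.01), Perc.10. = nr(0.10), Perc.50. = nr(0.50),
    Perc.90. = nr(0.90), Perc.99. = nr(0.99))
}
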