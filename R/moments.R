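#' Central moment of an image's pixel distribution
#'
#' `mu_k = mean((I - mean(I))^k)` over all pixels.
#'
#' @param image numeric matrix (or vector).
#' @param k moment order, one of 2, 3, 4.
#' @return scalar moment.
#' @export
central_moment <- function(image, k) {
  if (!k %in% c(2, 3, 4)) stopf("k must be 2, 3 or 4")
  x <- as.numeric(image)
  mean((x - mean(x))^k)
}

#' Central-moment statistical features of a spectrogram image
#'
#' Six descriptors of the spread and shape of the pixel intensity
#' distribution:
#' `F1 = log10(sqrt(mu2) + eps)` (log standard deviation),
#' `F2 = mu3` (third central moment), `F3 = log10(mu4 + eps)` (log fourth
#' central moment), and `F4 = sqrt(mu2^), F5 = mu3^, F6 = mu4^` where the
#' hatted moments are computed on the min-max normalized image, making
#' F4-F6 invariant to positive affine intensity transforms. `eps` keeps
#' flat (zero-variance) images finite.
#'
#' @param image numeric matrix.
#' @param eps additive constant inside both log10 terms (default 1e-12).
#' @param standardized if `TRUE`, F2/F5 are divided by `mu2^(3/2)` and
#'   F3/F6 use `mu4 / mu2^2` (classical skewness/kurtosis) instead of the
#'   raw moments.
#' @return named numeric vector `moment_F1` .. `moment_F6`.
#' @examples
#' moment_features(matrix(c(0, 0, 2, 2), 2, 2))
#' @export
moment_features <- function(image, eps = 1e-12, standardized = FALSE) {
  x <- as.numeric(image)
  mus <- vapply(2:4, function(k) central_moment(x, k), numeric(1L))
  xh <- as.numeric(minmax01(matrix(x)))
  mush <- vapply(2:4, function(k) central_moment(xh, k), numeric(1L))
  if (standardized) {
    s3 <- if (mus[1L] > 0) mus[1L]^1.5 else 1
    s4 <- if (mus[1L] > 0) mus[1L]^2 else 1
    sh3 <- if (mush[1L] > 0) mush[1L]^1.5 else 1
    sh4 <- if (mush[1L] > 0) mush[1L]^2 else 1
    mus[2L] <- mus[2L] / s3; mus[3L] <- mus[3L] / s4
    mush[2L] <- mush[2L] / sh3; mush[3L] <- mush[3L] / sh4
  }
  stats::setNames(
    c(log10(sqrt(mus[1L]) + eps), mus[2L], log10(mus[3L] + eps),
      sqrt(mush[1L]), mush[2L], mush[3L]),
    paste0("moment_F", 1:6))
}
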