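laws_kernels_3 <- list(L3 = c(1, 2, 1), E3 = c(1, 0, -1), S3 = c(1, -2, 1))
laws_kernels_5 <- list(L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1),
                       S5 = c(-1, 0, 2, 0, -1), W5 = c(-1, 2, 0, -2, 1),
                       R5 = c(1, -4, 6, -4, 1))

#' Laws' texture mask bank
#'
#' The 34 two-dimensional Laws masks: all 9 outer products of the
#' length-3 kernels L3 (level), E3 (edge), S3 (spot) and all 25 outer
#' products of the length-5 kernels L5, E5, S5, W5 (wave), R5 (ripple).
#' A mask named `<vert><horz>` (e.g. `L3E3`) is the column vector `vert`
#' times the row vector `horz`.
#'
#' @return named list of 34 matrices, the nine 3x3 masks first.
#' @examples
#' laws_masks()$L3E3
#' @export
laws_masks <- function() {
  bank <- list()
  for (kern in list(laws_kernels_3, laws_kernels_5)) {
    for (v in names(kern)) for (h in names(kern)) {
      bank[[paste0(v, h)]] <- outer(kern[[v]], kern[[h]])
    }
  }
  bank
}

# True 2-D convolution (kernel flipped), "same" output size, with either
# zero or replicate (nearest-edge) padding. Written as a shift-accumulate
# so results are bit-exact against a naive double-loop oracle (FFT-based
# convolution is not).
conv2_same <- function(img, k, border = c("zero", "replicate")) {
  border <- match.arg(border)
  kr <- nrow(k); kc <- ncol(k)
  if (kr %% 2L == 0L || kc %% 2L == 0L) stopf("kernel sides must be odd")
  n <- nrow(img); m <- ncol(img)
  kf <- k[kr:1, kc:1, drop = FALSE]  # flip -> convolution via correlation
  out <- matrix(0, n, m)
  cr <- (kr + 1L) / 2L; cc <- (kc + 1L) / 2L
  for (a in seq_len(kr)) {
    da <- a - cr
    for (b in seq_len(kc)) {
      w <- kf[a, b]
      if (w == 0) next
      db <- b - cc
      if (border == "replicate") {
        ri <- pmin(pmax(seq_len(n) + da, 1L), n)
        ci <- pmin(pmax(seq_len(m) + db, 1L), m)
        out <- out + w * img[ri, ci]
      } else {
        ri <- max(1L, 1L - da):min(n, n - da)
        ci <- max(1L, 1L - db):min(m, m - db)
        if (length(ri) < 1L || ci[1L] > ci[length(ci)]) next
        out[ri, ci] <- out[ri, ci] + w * img[ri + da, ci + db]
      }
    }
  }
  out
}

# Moving-window sum over a (2*half+1)^2 window with zero padding outside
# the image, computed with a summed-area table.
box_window_sum <- function(img, half = 7L) {
  n <- nrow(img); m <- ncol(img)
  p <- matrix(0, n + 2L * half, m + 2L * half)
  p[half + seq_len(n), half + seq_len(m)] <- img
  s <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed integral image
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  w <- 2L * half + 1L
  i1 <- seq_len(n); j1 <- seq_len(m)
  s[i1 + w, j1 + w, drop = FALSE] - s[i1, j1 + w, drop = FALSE] -
    s[i1 + w, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
}

#' Texture energy image for one Laws mask
#'
#' Convolves the image with the mask (true convolution, same size,
#' replicate padding so a constant image filtered by any zero-sum mask is
#' exactly zero everywhere), min-max normalizes the filtered image to
#' `[0, 1]` (a flat filtered image normalizes to all zeros), then sums
#' absolute values over a moving 15 x 15 window (zero padded at the
#' borders).
#'
#' @param image numeric matrix, at least 15 x 15.
#' @param mask one Laws mask (see [laws_masks()]).
#' @param window_half half-width of the energy window (default 7, i.e.
#'   a 15 x 15 window).
#' @param window_divisor divisor applied to the window sum (default 1,
#'   the literal windowed sum; set to `(2*window_half+1)^2` for a true
#'   moving average).
#' @return matrix of the same shape as `image` with values in
#'   `[0, (2*window_half+1)^2 / window_divisor]`.
#' @export
texture_energy <- function(image, mask, window_half = 7L,
                           window_divisor = 1) {
  image <- as.matrix(image)
  if (nrow(image) < 15L || ncol(image) < 15L)
    stopf("image must be at least 15 x 15")
  filt <- conv2_same(image, mask, border = "replicate")
  norm <- minmax01(filt)
  box_window_sum(abs(norm), half = window_half) / window_divisor
}

#' Laws' texture energy features of an image
#'
#' Mean (`ME`), population standard deviation (`STD`) and energy
#' (`EN`, the mean of squares, the literal printed formula despite its
#' customary "entropy" label) of the texture energy image of each of the
#' 34 Laws masks: 102 features.
#'
#' @inheritParams texture_energy
#' @return named numeric vector of length 102, names
#'   `laws_<mask>_<ME|STD|EN>` grouped by mask in bank order.
#' @export
texture_features <- function(image, window_half = 7L, window_divisor = 1) {
  bank <- laws_masks()
  out <- numeric(3L * length(bank))
  nms <- character(3L * length(bank))
  i <- 0L
  for (nm in names(bank)) {
    e <- texture_energy(image, bank[[nm]], window_half, window_divisor)
    mu <- mean(e)
    out[i + 1:3] <- c(mu, sqrt(mean((e - mu)^2)), mean(e^2))
    nms[i + 1:3] <- paste0("laws_", nm, "_", c("ME", "STD", "EN"))
    i <- i + 3L
  }
  stats::setNames(out, nms)
}
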