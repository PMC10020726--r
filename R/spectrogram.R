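#' Spectrogram configuration
#'
#' Parameters for building a square spectrogram image from a single-cycle
#' pulse wave. The default grid of square sizes is 20, 50, 100, 166 and
#' 250 pixels; the default configuration (Hamming window, 0% overlap,
#' 250 x 250) is the combination with the highest quality coefficients on
#' pulse-wave signals.
#'
#' @param window_type `"hamming"` or `"kaiser"`.
#' @param kaiser_alpha Kaiser shape parameter (required iff
#'   `window_type == "kaiser"`; 0.5, 3 and 5 pair with overlaps 0, 61 and
#'   70%).
#' @param overlap_pct window overlap percentage in `[0, 100)`.
#' @param out_size output image side in pixels.
#' @param scale `"magnitude"` or `"power"` of the short-time Fourier
#'   transform. Magnitude is the default so the image is a positive matrix
#'   as required by the Schrodinger-spectrum features.
#' @param window_frac STFT window length as a fraction of the signal
#'   length (window length = `floor(length * window_frac)`).
#' @param interp interpolation used to resize to the square image
#'   (`"linear"` bilinear or `"nearest"`).
#' @return An object of class `spectrogram_config`.
#' @export
spectrogram_config <- function(window_type = c("hamming", "kaiser"),
                               kaiser_alpha = NULL, overlap_pct = 0,
                               out_size = 250, scale = c("magnitude", "power"),
                               window_frac = 1 / 8,
                               interp = c("linear", "nearest")) {
  window_type <- match.arg(window_type)
  scale <- match.arg(scale)
  interp <- match.arg(interp)
  if (window_type == "kaiser" && is.null(kaiser_alpha))
    stopf("kaiser_alpha is required for the kaiser window")
  if (window_type == "hamming" && !is.null(kaiser_alpha))
    stopf("kaiser_alpha only applies to the kaiser window")
  if (overlap_pct < 0 || overlap_pct >= 100)
    stopf("overlap_pct must be in [0, 100)")
  if (out_size < 2) stopf("out_size must be >= 2")
  if (window_frac <= 0 || window_frac > 1)
    stopf("window_frac must be in (0, 1]")
  structure(list(window_type = window_type, kaiser_alpha = kaiser_alpha,
                 overlap_pct = overlap_pct, out_size = as.integer(out_size),
                 scale = scale, window_frac = window_frac, interp = interp),
            class = "spectrogram_config")
}

#' Compute a square spectrogram image of a single-cycle pulse wave
#'
#' Short-time Fourier transform with the configured window and overlap,
#' one-sided frequencies, magnitude (or power), bilinearly resampled to a
#' square `out_size x out_size` image and min-max scaled to `[0, 1]`.
#' Rows of the output are frequency, columns are time. The pre-resize
#' time/frequency axes and raw short-time magnitude matrix are kept for
#' inspection.
#'
#' @param wave a [pulse_wave()].
#' @param cfg a [spectrogram_config()].
#' @return An object of class `spectrogram` with fields `pixels`
#'   (out_size x out_size, in `[0,1]`), `config`, `time_axis_s`,
#'   `freq_axis_hz` and `stft` (pre-resize magnitude matrix).
#' @examples
#' w <- synthesize_pulse(8, 70, seed = 1)
#' s <- compute_spectrogram(w, spectrogram_config(out_size = 50))
#' dim(s$pixels)
#' @export
compute_spectrogram <- function(wave, cfg = spectrogram_config()) {
  stopifnot(inherits(wave, "pulse_wave"), inherits(cfg, "spectrogram_config"))
  x <- wave$samples
  n <- length(x)
  wl <- max(4L, floor(n * cfg$window_frac))
  if (n < 2L * wl)
    stopf("signal (%d samples) shorter than twice the window (%d)", n, wl)
  win <- if (cfg$window_type == "hamming") signal::hamming(wl) else
    signal::kaiser(wl, cfg$kaiser_alpha)
  overlap <- min(wl - 1L, floor(wl * cfg$overlap_pct / 100))
  sg <- signal::specgram(x, n = wl, Fs = wave$fs, window = win,
                         overlap = overlap)
  mag <- abs(sg$S)
  if (cfg$scale == "power") mag <- mag^2
  if (ncol(mag) < 2L || nrow(mag) < 2L)
    stopf("signal too short for a %d-sample window: STFT has %d x %d bins",
          wl, nrow(mag), ncol(mag))
  pixels <- resize_bilinear(mag, cfg$out_size, cfg$out_size, cfg$interp)
  pixels <- minmax01(pixels)
  structure(list(pixels = pixels, config = cfg,
                 time_axis_s = as.numeric(sg$t),
                 freq_axis_hz = as.numeric(sg$f), stft = mag),
            class = "spectrogram")
}

# resize a matrix to nr x nc by interpolation on the unit index grid
resize_bilinear <- function(m, nr, nc, method = "linear") {
  xs <- seq_len(ncol(m)); ys <- seq_len(nrow(m))
  xp <- seq(1, ncol(m), length.out = nc)
  yp <- seq(1, nrow(m), length.out = nr)
  grid <- expand.grid(y = yp, x = xp)
  v <- pracma::interp2(xs, ys, m, grid$x, grid$y, method = method)
  matrix(v, nrow = nr, ncol = nc)
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d x %d (%s window, %g%% overlap, %s)\n",
              nrow(x$pixels), ncol(x$pixels), x$config$window_type,
              x$config$overlap_pct, x$config$scale))
  invisible(x)
}

#' @export
plot.spectrogram <- function(x, ...) {
  image(t(x$pixels), useRaster = TRUE, xlab = "time (normalized)",
        ylab = "frequency (normalized)", ...)
  invisible(x)
}

#' Spectrogram quality coefficients
#'
#' Mean coefficient of variation of the image across frequency rows
#' (`Qf`), across time columns (`Qt`), and their product (`Qtf`). Larger
#' values indicate a spectrogram that better captures the variability of
#' the signal. Standard deviations are population (divisor N); rows or
#' columns with zero mean contribute 0 to the sums.
#'
#' @param spec a [spectrogram()] object or a nonnegative numeric matrix
#'   with frequency on the rows.
#' @return named list with `Qf`, `Qt`, `Qtf`.
#' @export
quality_coefficients <- function(spec) {
  m <- if (inherits(spec, "spectrogram")) spec$pixels else as.matrix(spec)
  if (length(m) == 0L) stopf("empty spectrogram")
  cv0 <- function(v) {
    mu <- mean(v)
    if (mu == 0) return(0)
    sqrt(mean((v - mu)^2)) / mu
  }
  qf <- mean(apply(m, 1L, cv0))
  qt <- mean(apply(m, 2L, cv0))
  list(Qf = qf, Qt = qt, Qtf = qf * qt)
}

#' Rank spectrogram configurations by quality coefficients
#'
#' Scores each candidate configuration by the mean `Qtf` over a set of
#' waves and returns the candidates ranked best first; ties are broken by
#' mean `Qf`.
#'
#' @param waves list of [pulse_wave()] objects.
#' @param cfgs list of [spectrogram_config()] candidates.
#' @return data.frame with columns `rank`, `cfg_index`, `mean_Qtf`,
#'   `mean_Qf`, `mean_Qt` plus the candidate list as attribute `cfgs`
#'   (ranked order).
#' @export
tune_spectrogram_params <- function(waves, cfgs) {
  if (length(cfgs) < 1L) stopf("at least one candidate configuration needed")
  if (length(waves) < 1L) stopf("at least one wave needed")
  scores <- t(vapply(cfgs, function(cfg) {
    qs <- vapply(waves, function(w) {
      q <- quality_coefficients(compute_spectrogram(w, cfg))
      c(q$Qtf, q$Qf, q$Qt)
    }, numeric(3L))
    rowMeans(qs)
  }, numeric(3L)))
  ord <- order(-scores[, 1L], -scores[, 2L])
  out <- data.frame(rank = seq_along(cfgs), cfg_index = ord,
                    mean_Qtf = scores[ord, 1L], mean_Qf = scores[ord, 2L],
                    mean_Qt = scores[ord, 3L])
  attr(out, "cfgs") <- cfgs[ord]
  out
}
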