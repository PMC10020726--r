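# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately written by a different route than the
# package internals (DFT assembly, double loops, exhaustive search).

rand_image <- function(n, seed, lo = 0, hi = 1) {
  withr::with_seed(seed, matrix(runif(n * n, lo, hi), n, n))
}

smooth_test_image <- function(n = 16) {
  g <- seq(0, 1, length.out = n)
  outer(g, g, function(a, b) exp(-((a - 0.5)^2 + (b - 0.5)^2) * 8))
}

# periodic pseudospectral second-derivative matrix assembled through the
# DFT: D2 = Re(F^H diag(-w^2) F) / n
d2_dft <- function(n) {
  k <- 0:(n - 1)
  w <- 2 * pi / n * ifelse(k <= n / 2, k, k - n)
  if (n %% 2 == 0) w[n / 2 + 1] <- pi
  fm <- exp(-2i * pi * outer(k, k) / n)
  Re(Conj(t(fm)) %*% diag(-w^2) %*% fm) / n
}

# dense eigensolve of the explicitly (DFT-)assembled Schrodinger operator
oracle_schrodinger_eigs <- function(signal, h) {
  n <- length(signal)
  op <- -h^2 * d2_dft(n) - diag(signal)
  ev <- eigen((op + t(op)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sort(ev[ev < 0])
}

# naive O(n^2 k^2) true 2-D convolution, replicate padded, same size
naive_conv2 <- function(img, k) {
  n <- nrow(img); m <- ncol(img)
  kr <- nrow(k); kc <- ncol(k)
  cr <- (kr + 1) / 2; cc <- (kc + 1) / 2
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (a in seq_len(kr)) for (b in seq_len(kc)) {
      ii <- min(max(i - (a - cr), 1), n)
      jj <- min(max(j - (b - cc), 1), m)
      acc <- acc + k[a, b] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# naive moving-window sum of a (2h+1)^2 window with zero padding
naive_window_sum <- function(img, half = 7) {
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ri <- max(1, i - half):min(n, i + half)
    ci <- max(1, j - half):min(m, j + half)
    out[i, j] <- sum(img[ri, ci])
  }
  out
}

# full Laws texture-energy oracle on one mask
oracle_texture_energy <- function(img, mask) {
  filt <- naive_conv2(img, mask)
  lo <- min(filt); hi <- max(filt)
  norm <- if (hi - lo <= 0) matrix(0, nrow(filt), ncol(filt)) else
    (filt - lo) / (hi - lo)
  naive_window_sum(abs(norm))
}

# F-statistic through R's own linear-model machinery
oracle_f_stat <- function(y, f) {
  if (stats::sd(f) == 0) return(0)
  as.numeric(stats::anova(stats::lm(y ~ f))["f", "F value"])
}

# exhaustive greedy MRMR-FCQ re-ranking, recomputing every score from the
# printed formula at every step
oracle_mrmr <- function(x, y, k = ncol(x)) {
  nms <- colnames(x)
  sel <- character(0)
  for (step in seq_len(k)) {
    cand <- setdiff(nms, sel)
    sc <- vapply(cand, function(f) {
      rel <- oracle_f_stat(y, x[, f])
      if (length(sel) == 0) return(rel)
      red <- mean(vapply(sel, function(s) {
        if (stats::sd(x[, s]) == 0 || stats::sd(x[, f]) == 0) return(0)
        abs(stats::cor(x[, f], x[, s]))
      }, numeric(1)))
      rel / max(red, 1e-12)
    }, numeric(1))
    sel <- c(sel, cand[order(-sc, cand)][1])
  }
  sel
}

# first local maximum after the global peak (reflected-wave arrival)
secondary_peak_index <- function(x) {
  pk <- which(diff(sign(diff(x))) == -2) + 1
  pk <- pk[pk > which.max(x)]
  if (length(pk) == 0) NA_integer_ else as.integer(pk[1])
}

tiny_cohort <- function(n_per_group = 8, n_groups = 3, seed = 11,
                        modality = "PPG") {
  generate_cohort(n_groups = n_groups, n_per_group = n_per_group,
                  modalities = modality, sites = "radial", seed = seed)
}
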