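#' Semi-classical analysis parameters
#'
#' @param h semi-classical parameter (> 0); smaller `h` yields more bound
#'   states (negative eigenvalues) and a richer representation.
#' @param gamma positive exponent applied to the negative eigenvalues,
#'   kappa = (-lambda)^gamma.
#' @return object of class `scsa_params`.
#' @export
scsa_params <- function(h, gamma = 1) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stopf("h must be a single positive number")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stopf("gamma must be a single positive number")
  structure(list(h = h, gamma = gamma), class = "scsa_params")
}

# Periodic Fourier pseudospectral second-derivative matrix on n points with
# unit grid spacing. Symmetric Toeplitz; entries depend only on |i - j|.
# This is the discretization used throughout the semi-classical signal
# analysis literature; a symmetrized central-difference matrix is available
# as a fallback.
fourier_d2_matrix <- function(n, method = c("fourier", "central")) {
  method <- match.arg(method)
  if (method == "central") {
    d <- rep(-2, n)
    m <- diag(d)
    idx <- seq_len(n - 1L)
    m[cbind(idx, idx + 1L)] <- 1
    m[cbind(idx + 1L, idx)] <- 1
    return(m)
  }
  feh <- 2 * pi / n
  k <- seq_len(n - 1L)
  if (n %% 2L == 0L) {
    diagv <- -pi^2 / (3 * feh^2) - 1 / 6
    offv <- -(-1)^k * 0.5 / sin(k * feh / 2)^2
  } else {
    # exact trigonometric-interpolation diagonal for odd n is +1/12
    diagv <- -pi^2 / (3 * feh^2) + 1 / 12
    offv <- -(-1)^k * 0.5 * cos(k * feh / 2) / sin(k * feh / 2)^2
  }
  first <- c(diagv, offv)  # row built from |i - j|
  m <- matrix(0, n, n)
  for (i in seq_len(n)) m[i, ] <- first[abs(i - seq_len(n)) + 1L]
  feh^2 * m
}

#' Negative spectrum of the 1-D semi-classical Schrodinger operator
#'
#' Eigenpairs of the symmetric discretization of
#' `-h^2 d^2/dx^2 - diag(signal)` on a unit-spaced grid. Only the negative
#' eigenvalues (bound states) are returned, in ascending order, together
#' with their discrete-L2-normalized eigenfunctions.
#'
#' @param signal numeric vector (length >= 3) interpreted as the potential
#'   well; typically a nonnegative image row or column.
#' @param h semi-classical parameter (> 0).
#' @param want_vectors if `FALSE` only eigenvalues are computed (faster).
#' @param method discretization of the second derivative: `"fourier"`
#'   (periodic pseudospectral, the default) or `"central"` differences.
#' @return list with `values` (negative eigenvalues, ascending; possibly
#'   length 0) and `vectors` (matrix with one column per eigenvalue, or
#'   `NULL`).
#' @examples
#' schrodinger_eigs_1d(rep(0, 8), h = 1)$values  # none: operator is PSD
#' @export
schrodinger_eigs_1d <- function(signal, h, want_vectors = TRUE,
                                method = c("fourier", "central")) {
  if (!is.numeric(signal) || length(signal) < 3L)
    stopf("signal must be numeric with length >= 3")
  if (!all(is.finite(signal))) stopf("signal must be finite")
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stopf("h must be a single positive number")
  n <- length(signal)
  op <- -h^2 * fourier_d2_matrix(n, method = method)
  diag(op) <- diag(op) - signal
  e <- eigen(op, symmetric = TRUE, only.values = !want_vectors)
  # strictly negative up to round-off: a PSD operator (zero signal) must
  # report no bound states even when LAPACK returns -1e-15
  tol <- 1e-10 * max(1, max(abs(e$values)))
  neg <- which(e$values < -tol)       # eigen() returns descending order
  vals <- rev(e$values[neg])          # ascending (most negative first)
  vecs <- NULL
  if (want_vectors && length(neg) > 0L) {
    vecs <- e$vectors[, rev(neg), drop = FALSE]
    # eigen() already returns unit Euclidean norm = unit discrete L2 norm
    # on a unit grid; renormalize defensively
    vecs <- sweep(vecs, 2L, sqrt(colSums(vecs^2)), "/")
  }
  list(values = vals, vectors = vecs)
}

#' Row/column Schrodinger decomposition of an image
#'
#' Applies the 1-D semi-classical eigendecomposition to every row and
#' every column of a square nonnegative image and assembles the three
#' kappa matrices used by the SCSA features: per-row kappas, per-column
#' kappas (each sorted descending within the row/column and zero-padded to
#' a rectangle) and their element-wise sum after zero-padded shape
#' alignment.
#'
#' @param image square nonnegative numeric matrix.
#' @param params [scsa_params()].
#' @param keep_eigenfunctions keep the L2-normalized eigenfunctions
#'   (needed for reconstruction, not for features).
#' @param method discretization passed to [schrodinger_eigs_1d()].
#' @return object of class `scsa_decomposition` with fields `row_kappas`,
#'   `col_kappas`, `combined_kappas`, `row_counts`, `col_counts`,
#'   `row_neg`, `col_neg` (lists of -lambda, descending), `row_eigfuncs`,
#'   `col_eigfuncs` (lists or `NULL`), `params`.
#' @export
scsa_decompose <- function(image, params, keep_eigenfunctions = FALSE,
                           method = c("fourier", "central")) {
  image <- as.matrix(image)
  if (nrow(image) != ncol(image)) stopf("image must be square")
  if (any(!is.finite(image))) stopf("image must be finite")
  if (any(image < 0)) stopf("image must be nonnegative")
  stopifnot(inherits(params, "scsa_params"))
  method <- match.arg(method)
  n <- nrow(image)

  solve_lines <- function(get_line) {
    neg <- vector("list", n)
    funs <- if (keep_eigenfunctions) vector("list", n) else NULL
    for (i in seq_len(n)) {
      e <- schrodinger_eigs_1d(get_line(i), params$h,
                               want_vectors = keep_eigenfunctions,
                               method = method)
      # e$values is ascending (most negative first), so -lambda is already
      # sorted descending and stays aligned with the eigenfunction columns
      neg[[i]] <- -e$values
      if (keep_eigenfunctions)
        funs[[i]] <- if (length(e$values) > 0L) e$vectors else matrix(0, n, 0L)
    }
    list(neg = neg, funs = funs)
  }
  rows <- solve_lines(function(i) image[i, ])
  cols <- solve_lines(function(j) image[, j])

  pad <- function(neg, width) {
    t(vapply(neg, function(v) c(v, rep(0, width - length(v))),
             numeric(width)))
  }
  kr <- max(c(0L, lengths(rows$neg)))
  kc <- max(c(0L, lengths(cols$neg)))
  width <- max(kr, kc, 1L)
  row_kappas <- pad(rows$neg, width)^params$gamma
  col_kappas <- pad(cols$neg, width)^params$gamma
  structure(list(row_kappas = row_kappas, col_kappas = col_kappas,
                 combined_kappas = row_kappas + col_kappas,
                 row_counts = lengths(rows$neg), col_counts = lengths(cols$neg),
                 row_neg = rows$neg, col_neg = cols$neg,
                 row_eigfuncs = rows$funs, col_eigfuncs = cols$funs,
                 params = params, n = n),
            class = "scsa_decomposition")
}

# semi-classical constant for the 2-D reconstruction,
# L^cl_{2,gamma} = Gamma(gamma + 1) / (4 pi Gamma(gamma + 2))
l_cl_2d <- function(gamma) gamma(gamma + 1) / (4 * pi * gamma(gamma + 2))

#' 2-D SCSA image reconstruction by separation of variables
#'
#' Reconstructs a positive square image from the Schrodinger spectra of
#' its rows and columns:
#' pixel `(i,j) = [ h^2 / L_cl * sum_{k,r} ((-beta_{i,k}) + (-rho_{j,r}))^gamma
#' * psi^2_{i,k}(j) * phi^2_{j,r}(i) ]^(1/(1+gamma))`
#' where `beta`/`rho` are the negative eigenvalues of row i / column j,
#' `psi`/`phi` their eigenfunctions and
#' `L_cl = Gamma(gamma+1) / (4 pi Gamma(gamma+2))`. As `h` decreases the
#' reconstruction converges to the original image.
#'
#' @param image square nonnegative numeric matrix (or an
#'   `scsa_decomposition` with eigenfunctions kept).
#' @param params [scsa_params()] (ignored when a decomposition is given).
#' @param method discretization passed to [schrodinger_eigs_1d()].
#' @return nonnegative matrix of the same shape. If no row and no column
#'   has a negative eigenvalue the reconstruction is all zero.
#' @export
scsa2d_reconstruct <- function(image, params, method = c("fourier", "central")) {
  dec <- if (inherits(image, "scsa_decomposition")) image else
    scsa_decompose(image, params, keep_eigenfunctions = TRUE,
                   method = method)
  if (is.null(dec$row_eigfuncs))
    stopf("decomposition lacks eigenfunctions; rerun with keep_eigenfunctions = TRUE")
  n <- dec$n
  h <- dec$params$h
  gam <- dec$params$gamma
  kmax <- max(c(0L, dec$row_counts))
  rmax <- max(c(0L, dec$col_counts))
  if (kmax == 0L && rmax == 0L) return(matrix(0, n, n))
  if (kmax == 0L || rmax == 0L) return(matrix(0, n, n))

  # nb[i, k] = -beta_{i,k} (0-padded); Psi2[[k]][i, j] = psi^2_{i,k}(j)
  nb <- matrix(0, n, kmax)
  nc_ <- matrix(0, n, rmax)
  psi2 <- lapply(seq_len(kmax), function(k) matrix(0, n, n))
  phi2 <- lapply(seq_len(rmax), function(r) matrix(0, n, n))
  for (i in seq_len(n)) {
    ki <- dec$row_counts[i]
    if (ki > 0L) {
      nb[i, seq_len(ki)] <- dec$row_neg[[i]]
      for (k in seq_len(ki)) psi2[[k]][i, ] <- dec$row_eigfuncs[[i]][, k]^2
    }
    ri <- dec$col_counts[i]
    if (ri > 0L) {
      nc_[i, seq_len(ri)] <- dec$col_neg[[i]]
      for (r in seq_len(ri)) phi2[[r]][, i] <- dec$col_eigfuncs[[i]][, r]^2
    }
  }
  s <- matrix(0, n, n)
  for (k in seq_len(kmax)) {
    pk <- psi2[[k]]
    bk <- nb[, k]
    for (r in seq_len(rmax)) {
      term <- outer(bk, nc_[, r], "+")
      # zero out pairs where either line lacks this rank
      s <- s + term^gam * pk * phi2[[r]]
    }
  }
  (pmax(s, 0) * h^2 / l_cl_2d(gam))^(1 / (1 + gam))
}

#' Minimum semi-classical parameter of an image
#'
#' Sampling-theorem-based lower bound for `h` extended from 1-D signals to
#' images: `hr_min(i) = T_s * sqrt(max(row_i)) / pi` for every row,
#' `hc_min(j)` analogously for every column, `hm_min(i,j)` their mean, and
#' the returned value is the maximum over all pixels (the safest operating
#' point, avoiding aliasing in the representation).
#'
#' @param image square nonnegative numeric matrix with a positive entry,
#'   or a [compute_spectrogram()] result.
#' @param ts pixel spacing (default 1: the resized image has no physical
#'   axis).
#' @return scalar `h_min`.
#' @examples
#' h_min_image(matrix(c(1, 4, 4, 1), 2, 2))  # 2 / pi
#' @export
h_min_image <- function(image, ts = 1) {
  m <- if (inherits(image, "spectrogram")) image$pixels else as.matrix(image)
  if (max(m) <= 0) stopf("h_min is undefined for an all-zero image")
  hr <- ts * sqrt(apply(m, 1L, max)) / pi
  hc <- ts * sqrt(apply(m, 2L, max)) / pi
  (max(hr) + max(hc)) / 2
}

#' Select gamma by reconstruction quality
#'
#' Reconstructs the image with each gamma in the grid at a fixed `h` and
#' returns the gamma maximizing the structural similarity (SSIM) between
#' the original and the reconstruction, both min-max scaled to `[0,1]`.
#' Ties are broken by higher PSNR, then by smaller gamma.
#'
#' @param image square nonnegative numeric matrix.
#' @param h semi-classical parameter (defaults to [h_min_image()]).
#' @param gamma_grid candidate gammas.
#' @return list with `gamma`, and a data.frame `report` of SSIM/PSNR per
#'   candidate.
#' @export
select_gamma <- function(image, h = NULL,
                         gamma_grid = c(0.5, 1, 2, 3, 4, 5)) {
  m <- if (inherits(image, "spectrogram")) image$pixels else as.matrix(image)
  if (length(gamma_grid) < 1L) stopf("gamma_grid must be nonempty")
  if (is.null(h)) h <- h_min_image(m)
  ref <- minmax01(m)
  rep_df <- data.frame(gamma = gamma_grid, ssim = NA_real_, psnr = NA_real_)
  for (i in seq_along(gamma_grid)) {
    rec <- scsa2d_reconstruct(m, scsa_params(h, gamma_grid[i]))
    rec <- minmax01(rec)
    rep_df$ssim[i] <- ssim(ref, rec)
    rep_df$psnr[i] <- psnr(ref, rec)
  }
  ord <- order(-rep_df$ssim, -rep_df$psnr, rep_df$gamma)
  list(gamma = rep_df$gamma[ord[1L]], report = rep_df)
}

#' Structural similarity index (SSIM) of two images
#'
#' Standard Gaussian-weighted SSIM (11 x 11 window, sigma 1.5,
#' C1 = (0.01 L)^2, C2 = (0.03 L)^2) averaged over the image, for images
#' on a `[0, L]` intensity scale.
#'
#' @param x,y numeric matrices of equal shape.
#' @param L dynamic range (default 1).
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, L = 1) {
  stopifnot(all(dim(x) == dim(y)))
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  g <- outer(dnorm(seq(-5, 5), sd = 1.5), dnorm(seq(-5, 5), sd = 1.5))
  g <- g / sum(g)
  win <- min(dim(x))
  if (win < 11L) {  # shrink the window for tiny images
    k <- max(3L, win - (1 - win %% 2L))
    half <- (k - 1L) / 2L
    g <- outer(dnorm(seq(-half, half), sd = 1.5),
               dnorm(seq(-half, half), sd = 1.5))
    g <- g / sum(g)
  }
  mu_x <- conv2_same(x, g); mu_y <- conv2_same(y, g)
  sxx <- conv2_same(x * x, g) - mu_x^2
  syy <- conv2_same(y * y, g) - mu_y^2
  sxy <- conv2_same(x * y, g) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + c1) * (2 * sxy + c2)
  den <- (mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2)
  mean(num / den)
}

#' Peak signal-to-noise ratio in dB
#'
#' @param x reference image.
#' @param y test image.
#' @param L dynamic range.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(x, y, L = 1) {
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(L^2 / mse)
}

#' @importFrom stats dnorm
NULL

scsa_feature_stats <- c("INV1", "INV2", "INV3", "K1", "K2", "K3",
                        "E1", "E2", "E3", "Rh", "MRh", "Nh")

#' Schrodinger-spectrum (SCSA) features of a spectrogram image
#'
#' Twelve features from each of the three kappa matrices (per-row,
#' per-column and combined), 36 in total. With `kappa = (-lambda)^gamma`
#' and `h` the operating semi-classical parameter:
#' the spectral invariants `INV1 = c1 * h * sum(kappa)`,
#' `INV2 = c2 * h^3 * sum(kappa^3)`, `INV3 = c3 * h^7 * sum(kappa^7)`
#' (default constants 4, 16, 256, configurable via `inv_consts`);
#' `K_n` the mean over rows of the rank-n kappa and `E_n` the mean of
#' `kappa^(1/gamma)` (n = 1, 2, 3); `Rh = max(kappa) / h`;
#' `MRh = median(kappa over actual eigenvalues) / h`; `Nh` the mean
#' eigenvalue count per line. `h` defaults to [h_min_image()] of the
#' image, the proposed operating point.
#'
#' @param image square nonnegative matrix or [compute_spectrogram()]
#'   result; may also be an `scsa_decomposition`.
#' @param params optional [scsa_params()]; when `NULL`, `h = h_min_image`
#'   and `gamma = gamma` argument.
#' @param gamma gamma used when `params` is `NULL` (default 1).
#' @param inv_consts numeric length-3 multipliers of the three invariants.
#' @param method discretization passed to [schrodinger_eigs_1d()].
#' @return named numeric vector of length 36
#'   (`scsa_<row|col|sum>_<stat>`), with attributes `empty_spectrum`
#'   (flag), `h`, `gamma` and `kappa_diagnostics` (mean/sd of kappa per
#'   matrix, outside the 36-vector).
#' @export
scsa_features <- function(image, params = NULL, gamma = 1,
                          inv_consts = c(4, 16, 256),
                          method = c("fourier", "central")) {
  empty_names <- as.vector(outer(scsa_feature_stats,
                                 c("row", "col", "sum"),
                                 function(s, m) paste0("scsa_", m, "_", s)))
  if (inherits(image, "scsa_decomposition")) {
    dec <- image
  } else {
    m <- if (inherits(image, "spectrogram")) image$pixels else as.matrix(image)
    if (max(m) <= 0 || all(m == 0)) {
      out <- stats::setNames(rep(0, 36L), empty_names)
      attr(out, "empty_spectrum") <- TRUE
      return(out)
    }
    if (is.null(params)) params <- scsa_params(h_min_image(m), gamma)
    dec <- scsa_decompose(m, params, keep_eigenfunctions = FALSE,
                          method = method)
  }
  h <- dec$params$h; gam <- dec$params$gamma
  counts <- list(row = dec$row_counts, col = dec$col_counts,
                 sum = pmax(dec$row_counts, dec$col_counts))
  mats <- list(row = dec$row_kappas, col = dec$col_kappas,
               sum = dec$combined_kappas)
  empty <- all(dec$row_counts == 0L) && all(dec$col_counts == 0L)
  feats <- numeric(0)
  diag_list <- list()
  for (nm in names(mats)) {
    km <- mats[[nm]]
    cnt <- counts[[nm]]
    mask <- outer(cnt, seq_len(ncol(km)), ">=")  # TRUE at real eigenvalues
    kvals <- km[mask]
    f <- c(
      INV1 = inv_consts[1L] * h * sum(km),
      INV2 = inv_consts[2L] * h^3 * sum(km^3),
      INV3 = inv_consts[3L] * h^7 * sum(km^7),
      K1 = mean(km[, 1L]),
      K2 = if (ncol(km) >= 2L) mean(km[, 2L]) else 0,
      K3 = if (ncol(km) >= 3L) mean(km[, 3L]) else 0,
      E1 = mean(km[, 1L]^(1 / gam)),
      E2 = if (ncol(km) >= 2L) mean(km[, 2L]^(1 / gam)) else 0,
      E3 = if (ncol(km) >= 3L) mean(km[, 3L]^(1 / gam)) else 0,
      Rh = max(km) / h,
      MRh = if (length(kvals) > 0L) median(kvals) / h else 0,
      Nh = mean(cnt)
    )
    names(f) <- paste0("scsa_", nm, "_", scsa_feature_stats)
    feats <- c(feats, f)
    diag_list[[nm]] <- c(mean_kappa = if (length(kvals)) mean(kvals) else 0,
                         sd_kappa = if (length(kvals) > 1L) sd(kvals) else 0)
  }
  if (empty) feats[] <- 0
  attr(feats, "empty_spectrum") <- empty
  attr(feats, "h") <- h
  attr(feats, "gamma") <- gam
  attr(feats, "kappa_diagnostics") <- diag_list
  feats
}
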