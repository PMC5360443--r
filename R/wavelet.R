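#' Orthonormal discrete Meyer wavelet transform (periodic, FFT-domain)
#'
#' The scrambling engine needs a six-level 2D wavelet decomposition whose
#' round trip is lossless to numerical precision, so that rotating detail
#' coefficients is the *only* thing that alters a frame. The Meyer wavelet is
#' band-limited and its quadrature-mirror pair can be evaluated exactly on any
#' even DFT grid, which makes an FFT-domain periodic implementation exactly
#' orthonormal: analysis is the adjoint of synthesis and
#' `reconstruct(decompose(x)) == x` to machine precision.
#'
#' @name meyer-dwt
#' @keywords internal
NULL

# Meyer auxiliary polynomial, C^3 ramp from 0 to 1 on [0,1]
meyer_nu <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
}

# Lowpass QMF H(omega) on the length-n DFT grid; real, even,
# H(0) = sqrt(2), and H(w)^2 + H(w + pi)^2 = 2 exactly.
meyer_lowpass <- function(n) {
  stopifnot(n %% 2 == 0)
  omega <- 2 * pi * (0:(n - 1)) / n
  omega[omega > pi] <- omega[omega > pi] - 2 * pi
  a <- abs(omega)
  H <- numeric(n)
  H[a <= pi / 3] <- sqrt(2)
  mid <- a > pi / 3 & a < 2 * pi / 3
  H[mid] <- sqrt(2) * cos(pi / 2 * meyer_nu(3 * a[mid] / pi - 1))
  H
}

# Highpass G(omega) = exp(-i omega) * H(omega + pi)
meyer_highpass <- function(n) {
  H <- meyer_lowpass(n)
  Hs <- c(H[(n / 2 + 1):n], H[1:(n / 2)]) # H at omega + pi
  k <- 0:(n - 1)
  exp(-1i * 2 * pi * k / n) * Hs
}

# One analysis step along columns: x (n x m) -> list(a, d), each n/2 x m.
dwt_step_cols <- function(x) {
  n <- nrow(x)
  h <- n / 2
  H <- meyer_lowpass(n)
  Gc <- Conj(meyer_highpass(n))
  X <- stats::mvfft(x)
  lo <- 1:h
  hi <- (h + 1):n
  Ahat <- 0.5 * (H[lo] * X[lo, , drop = FALSE] + H[hi] * X[hi, , drop = FALSE])
  Dhat <- 0.5 * (Gc[lo] * X[lo, , drop = FALSE] + Gc[hi] * X[hi, , drop = FALSE])
  list(
    a = Re(stats::mvfft(Ahat, inverse = TRUE)) / h,
    d = Re(stats::mvfft(Dhat, inverse = TRUE)) / h
  )
}

# One synthesis step along columns: a, d (h x m) -> x (2h x m).
idwt_step_cols <- function(a, d) {
  h <- nrow(a)
  n <- 2 * h
  H <- meyer_lowpass(n)
  G <- meyer_highpass(n)
  Ahat <- stats::mvfft(a)
  Dhat <- stats::mvfft(d)
  idx <- c(1:h, 1:h) # spectra of upsampled signals are h-periodic
  Xhat <- H * Ahat[idx, , drop = FALSE] + G * Dhat[idx, , drop = FALSE]
  Re(stats::mvfft(Xhat, inverse = TRUE)) / n
}

# One 2D analysis step: x (n x n) -> LL, LH (horizontal detail),
# HL (vertical detail), HH (diagonal).
dwt2_step <- function(x) {
  cols <- dwt_step_cols(x) # filter along rows-dimension (columns of matrix)
  la <- dwt_step_cols(t(cols$a))
  ld <- dwt_step_cols(t(cols$d))
  list(
    ll = t(la$a),
    h  = t(la$d), # lowpass rows-dim, highpass cols-dim: horizontal contours
    v  = t(ld$a),
    d  = t(ld$d)
  )
}

idwt2_step <- function(ll, h, v, d) {
  a <- t(idwt_step_cols(t(ll), t(h)))
  b <- t(idwt_step_cols(t(v), t(d)))
  idwt_step_cols(a, b)
}

#' Six-level discrete Meyer wavelet decomposition of a grayscale image
#'
#' Decomposes a square image (side a power of 2, divisible by `2^levels`)
#' into a coarse approximation plus, per level, three detail bands
#' (horizontal, vertical, diagonal). Level 1 is the finest scale. The
#' transform is orthonormal: energies add up and the round trip through
#' [swift_reconstruct()] is exact to numerical precision.
#'
#' @param image numeric matrix, square, side divisible by `2^levels`,
#'   luminance values (conventionally in `[0, 1]`).
#' @param levels integer number of decomposition levels (default 6).
#' @return an object of class `"swift_decomposition"`: a list with
#'   `approximation` (matrix at the coarsest scale) and `details`, a list of
#'   length `levels`, each element a list with matrices `h`, `v`, `d`.
#' @examples
#' img <- synthetic_image("face", size = 64)
#' dec <- swift_decompose(img, levels = 3)
#' max(abs(swift_reconstruct(dec) - img)) < 1e-9
#' @export
swift_decompose <- function(image, levels = 6L) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("`image` must be a square matrix")
  if (any(!is.finite(image))) stop("`image` must contain only finite values")
  n <- nrow(image)
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1")
  if (n %% (2^levels) != 0)
    stop("image side (", n, ") is not divisible by 2^levels (", 2^levels, ")")
  details <- vector("list", levels)
  cur <- image
  for (l in seq_len(levels)) {
    s <- dwt2_step(cur)
    details[[l]] <- list(h = s$h, v = s$v, d = s$d)
    cur <- s$ll
  }
  structure(list(approximation = cur, details = details, side = n,
                 levels = levels),
            class = "swift_decomposition")
}

#' Inverse discrete Meyer wavelet transform
#'
#' @param dec a `"swift_decomposition"` from [swift_decompose()].
#' @return the reconstructed image matrix.
#' @export
swift_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "swift_decomposition"))
  cur <- dec$approximation
  for (l in rev(seq_len(dec$levels))) {
    dl <- dec$details[[l]]
    cur <- idwt2_step(cur, dl$h, dl$v, dl$d)
  }
  cur
}

#' Per-level wavelet detail energy
#'
#' Sum of squared detail coefficients at each level (plus the approximation
#' band), used to check that scrambling conserves the energy distribution
#' across scales.
#'
#' @param dec a `"swift_decomposition"`.
#' @return named numeric vector: one entry per detail level plus
#'   `"approximation"`.
#' @export
wavelet_energy <- function(dec) {
  stopifnot(inherits(dec, "swift_decomposition"))
  e <- vapply(dec$details, function(dl) {
    sum(dl$h^2) + sum(dl$v^2) + sum(dl$d^2)
  }, numeric(1))
  c(stats::setNames(e, paste0("level", seq_along(e))),
    approximation = sum(dec$approximation^2))
}
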