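# Centered FFT helpers. All grids in this package are odd-sized and centered,
# so the zero frequency / focal origin is an exact sample at index (N+1)/2.

#' @keywords internal
fftshift_vec <- function(v) {
  n <- length(v)
  m <- (n - 1L) %/% 2L
  v[c((n - m + 1L):n, 1L:(n - m))]
}

#' @keywords internal
ifftshift_vec <- function(v) {
  n <- length(v)
  m <- (n - 1L) %/% 2L
  v[c((m + 1L):n, 1L:m)]
}

#' @keywords internal
fftshift_mat <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  m1 <- (n1 - 1L) %/% 2L; m2 <- (n2 - 1L) %/% 2L
  x[c((n1 - m1 + 1L):n1, 1L:(n1 - m1)), c((n2 - m2 + 1L):n2, 1L:(n2 - m2))]
}

#' @keywords internal
ifftshift_mat <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  m1 <- (n1 - 1L) %/% 2L; m2 <- (n2 - 1L) %/% 2L
  x[c((m1 + 1L):n1, 1L:m1), c((m2 + 1L):n2, 1L:m2)]
}

# Unitary centered 2D transforms: sum(|x|^2) is preserved exactly, which makes
# Parseval / power-conservation checks trivial identities.

#' @keywords internal
fft2c <- function(x) {
  fftshift_mat(stats::fft(ifftshift_mat(x))) / sqrt(length(x))
}

#' @keywords internal
ifft2c <- function(x) {
  fftshift_mat(stats::fft(ifftshift_mat(x), inverse = TRUE)) / sqrt(length(x))
}

# Unitary centered 1D transform along the rows (first margin) of a matrix,
# i.e. each column is transformed independently.
#' @keywords internal
ifft1c_cols <- function(x) {
  n <- nrow(x)
  m <- (n - 1L) %/% 2L
  idx_in <- c((m + 1L):n, 1L:m)           # ifftshift
  idx_out <- c((n - m + 1L):n, 1L:(n - m)) # fftshift
  y <- stats::mvfft(x[idx_in, , drop = FALSE], inverse = TRUE) / sqrt(n)
  y[idx_out, , drop = FALSE]
}

#' @keywords internal
fft1c_cols <- function(x) {
  n <- nrow(x)
  m <- (n - 1L) %/% 2L
  idx_in <- c((m + 1L):n, 1L:m)
  idx_out <- c((n - m + 1L):n, 1L:(n - m))
  y <- stats::mvfft(x[idx_in, , drop = FALSE]) / sqrt(n)
  y[idx_out, , drop = FALSE]
}

# n-dimensional shift for 3D arrays (used by the deconvolution code).
#' @keywords internal
ifftshift_arr <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    m <- (n - 1L) %/% 2L
    c((m + 1L):n, if (m > 0L) 1L:m)
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' @keywords internal
fftshift_arr <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    m <- (n - 1L) %/% 2L
    c((n - m + 1L):n, 1L:(n - m))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Bilinear interpolation of a matrix z (rows indexed by xg, cols by yg) onto
# the tensor grid xout x yout; points outside the source grid return `fill`.
#' @keywords internal
bilinear_grid <- function(z, xg, yg, xout, yout, fill = 0) {
  nx <- length(xg); ny <- length(yg)
  ix <- findInterval(xout, xg)
  iy <- findInterval(yout, yg)
  ok_x <- ix >= 1L & ix < nx
  ok_y <- iy >= 1L & iy < ny
  ix1 <- pmin(pmax(ix, 1L), nx - 1L)
  iy1 <- pmin(pmax(iy, 1L), ny - 1L)
  tx <- (xout - xg[ix1]) / (xg[ix1 + 1L] - xg[ix1])
  ty <- (yout - yg[iy1]) / (yg[iy1 + 1L] - yg[iy1])
  v <- outer(1 - tx, 1 - ty) * z[ix1, iy1, drop = FALSE] +
    outer(tx, 1 - ty) * z[ix1 + 1L, iy1, drop = FALSE] +
    outer(1 - tx, ty) * z[ix1, iy1 + 1L, drop = FALSE] +
    outer(tx, ty) * z[ix1 + 1L, iy1 + 1L, drop = FALSE]
  v[!ok_x, ] <- fill
  v[, !ok_y] <- fill
  v
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
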