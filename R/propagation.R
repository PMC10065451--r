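#' Stationary excitation PSF at a propagation offset
#'
#' Intensity `|E(x, z; y)|^2` of the stationary (unswept) excitation pattern
#' at plane `y`.
#'
#' @param pupil A [pupil_field()].
#' @param grids A [make_grids()] grid set.
#' @param y Propagation offset (nm).
#' @return An object of class `psf_slice`: `values` (nonnegative matrix,
#'   rows `z`, columns `x`), `y_offset`, `x_axis`, `z_axis`.
#' @export
excitation_psf <- function(pupil, grids, y = 0) {
  foc <- pupil_to_focal(pupil, grids, y = y)
  structure(list(values = Mod(foc$values)^2, y_offset = y,
                 x_axis = grids$x_axis, z_axis = grids$x_axis),
            class = "psf_slice")
}

#' @export
print.psf_slice <- function(x, ...) {
  cat(sprintf("<psf_slice> %d x %d at y = %.0f nm\n",
              nrow(x$values), ncol(x$values), x$y_offset))
  invisible(x)
}

#' Excitation OTF at a propagation offset
#'
#' Transform of the stationary excitation PSF at plane `y`; at `y = 0` this
#' equals the autocorrelation of the pupil electric field, and at `y != 0`
#' it carries the defocus phase factors of the propagated field.
#'
#' @inheritParams excitation_psf
#' @return An [otf_map] object: complex `values` (rows `kz`, columns `kx`),
#'   DC-normalized, with `na_axis` in NA units and `y_offset`.
#' @export
excitation_otf <- function(pupil, grids, y = 0) {
  psf <- excitation_psf(pupil, grids, y = y)
  O <- fft2c(psf$values)
  ctr <- (grids$N_k + 1L) %/% 2L
  O <- O / O[ctr, ctr]
  structure(list(values = O, y_offset = y, na_axis = grids$na_axis,
                 normalization = "DC"),
            class = "otf_map")
}

#' @export
print.otf_map <- function(x, ...) {
  cat(sprintf("<otf_map> %d x %d at y = %.0f nm, DC-normalized\n",
              nrow(x$values), ncol(x$values), x$y_offset))
  invisible(x)
}

#' Swept light sheet: intensity profile and axial OTF versus propagation
#'
#' Sweeping the excitation pattern along `x` time-averages it, so the swept
#' sheet intensity is the `x`-average of the stationary PSF at each `y`, and
#' its axial excitation OTF is the `kx = 0` line of the excitation OTF. Both
#' are computed per propagation plane.
#'
#' @param pupil A [pupil_field()].
#' @param grids A [make_grids()] grid set.
#' @param y_planes Propagation offsets (nm); defaults to `grids$y_planes`.
#' @return An object of class `swept_sheet`: `intensity` (matrix, rows = y
#'   planes, columns = z samples, nonnegative), `axial_otf` (complex matrix,
#'   same layout over `kz`, DC-normalized per plane), `y_planes`, `z_axis`,
#'   `kz_na` (axial frequency axis in NA units), and the grid config.
#' @export
swept_sheet <- function(pupil, grids, y_planes = NULL) {
  P <- if (inherits(pupil, "pupil_field")) pupil$values else pupil
  check_propagating(P, grids)
  y_planes <- y_planes %||% grids$y_planes
  ky <- ky_map(grids)
  ky[is.na(ky)] <- 0
  N <- grids$N_k
  ctr <- (N + 1L) %/% 2L
  nz <- which(colSums(Mod(P)) > 0)   # empty pupil columns contribute nothing
  Pnz <- P[, nz, drop = FALSE]
  kynz <- ky[, nz, drop = FALSE]
  intensity <- matrix(0, length(y_planes), N)
  axial_otf <- matrix(0 + 0i, length(y_planes), N)
  for (i in seq_along(y_planes)) {
    Eh <- ifft1c_cols(Pnz * exp(1i * kynz * y_planes[i]))
    prof <- rowSums(Mod(Eh)^2) / N   # mean over x of |E(x, z)|^2
    intensity[i, ] <- prof
    ao <- fftshift_vec(stats::fft(ifftshift_vec(prof)))
    axial_otf[i, ] <- ao / ao[ctr]
  }
  structure(list(intensity = intensity, axial_otf = axial_otf,
                 y_planes = y_planes, z_axis = grids$x_axis,
                 kz_na = grids$na_axis, config = grids$config,
                 spec = if (inherits(pupil, "pupil_field")) pupil$spec),
            class = "swept_sheet")
}

#' @export
print.swept_sheet <- function(x, ...) {
  cat(sprintf("<swept_sheet> %d y planes x %d z samples\n",
              nrow(x$intensity), ncol(x$intensity)))
  invisible(x)
}

# row index of the plane nearest to y (error if far off the sampled range)
#' @keywords internal
sheet_plane_index <- function(sheet, y) {
  i <- which.min(abs(sheet$y_planes - y))
  tol <- if (length(sheet$y_planes) > 1L)
    max(diff(sort(sheet$y_planes))) / 2 + 1e-9 else 1e-9
  if (abs(sheet$y_planes[i] - y) > tol)
    stop(sprintf("requested y = %g nm is not among the sampled sheet planes",
                 y), call. = FALSE)
  i
}

# Sheet axial profile at plane y evaluated on an arbitrary z grid by direct
# Fourier summation of the (band-limited) axial OTF -- exact interpolation.
#' @keywords internal
sheet_profile_at <- function(sheet, y, z_out) {
  i <- sheet_plane_index(sheet, y)
  o <- sheet$axial_otf[i, ]
  keep <- Mod(o) > 0
  kz <- 2 * pi * sheet$kz_na[keep] / sheet$config$lambda_exc  # rad/nm
  prof <- as.vector(Re(exp(1i * outer(z_out, kz)) %*% o[keep]))
  pmax(prof, 0)
}

#' Scalar detection OTF (axial slice)
#'
#' Computes the widefield detection OTF on the `(kx, kz)` plane at
#' `ky = 0` -- the classic "bowtie" with its missing cone -- from a scalar
#' Debye model: the amplitude point response is the transform of the
#' uniform spherical pupil cap of half-angle `asin(NA_det / n)` at the
#' emission wavelength; the PSF is projected along `y` and transformed over
#' `(x, z)`. The result is resampled onto the excitation pupil grid so it
#' can be convolved directly with excitation OTFs.
#'
#' Support geometry: lateral radius `2 NA_det / lambda_det` (cycles/nm) and
#' maximum axial half-width `(n - sqrt(n^2 - NA_det^2)) / lambda_det` at
#' lateral offset `NA_det / lambda_det`, with `OTF(0, kz) = 0` inside the
#' missing cone.
#'
#' @param config An [optical_config()].
#' @param grids A [make_grids()] grid set (defines the target sampling).
#' @param n_det Internal detection grid size (odd); controls the accuracy of
#'   the numerical model.
#' @return An object of class `detection_otf`: `slice_values` (real matrix,
#'   rows `kz`, columns `kx`, on `grids$na_axis` in excitation NA units,
#'   DC = 1), `support_mask`, and the analytic support radii as fields
#'   `lateral_support`, `bowtie_half_width` (cycles/nm).
#' @export
detection_otf <- function(config, grids, n_det = 351L) {
  stopifnot(inherits(config, "optical_config"), inherits(grids, "grid_set"))
  n_det <- as.integer(n_det)
  if (n_det %% 2L == 0L) n_det <- n_det + 1L
  lam <- config$lambda_det
  n <- config$n_medium
  k_det <- 2 * pi * n / lam
  dx <- lam / (4.4 * config$NA_det)      # Nyquist for the lateral support
  half <- (n_det - 1L) %/% 2L
  ax <- seq.int(-half, half) * dx
  df <- 1 / (n_det * dx)
  fax <- seq.int(-half, half) * df       # cycles/nm
  kperp2 <- outer((2 * pi * fax)^2, (2 * pi * fax)^2, `+`)
  cap <- kperp2 <= (2 * pi * config$NA_det / lam)^2
  kz_cap <- sqrt(pmax(k_det^2 - kperp2, 0))
  P_xz <- matrix(0, n_det, n_det)        # rows x, cols z
  for (iz in seq_len(n_det)) {
    A <- ifft2c(ifelse(cap, exp(1i * kz_cap * ax[iz]), 0 + 0i))
    P_xz[, iz] <- rowSums(Mod(A)^2)      # project along y
  }
  O <- fft2c(P_xz)                       # rows kx, cols kz
  O <- t(O)                              # rows kz, cols kx
  ctr <- half + 1L
  O <- Re(O / O[ctr, ctr])
  # resample onto the excitation grid (NA units -> cycles/nm via lambda_exc)
  f_target <- grids$na_axis / config$lambda_exc
  slice <- bilinear_grid(O, fax, fax, f_target, f_target, fill = 0)
  lateral_support <- 2 * config$NA_det / lam
  bowtie <- (n - sqrt(n^2 - config$NA_det^2)) / lam
  support_mask <- abs(slice) > 1e-3
  structure(list(slice_values = slice, support_mask = support_mask,
                 na_axis = grids$na_axis,
                 lateral_support = lateral_support,
                 bowtie_half_width = bowtie, config = config),
            class = "detection_otf")
}

#' @export
print.detection_otf <- function(x, ...) {
  cat(sprintf(paste0("<detection_otf> lateral support %.4g /nm, bowtie ",
                     "half-width %.4g /nm\n"),
              x$lateral_support, x$bowtie_half_width))
  invisible(x)
}

#' Scalar detection PSF sampled on a volume grid
#'
#' Radially symmetric scalar Debye point response
#' `A(rho, z) = integral_0^thetamax J0(k rho sin t) exp(i k z cos t) sin t dt`
#' evaluated on a Cartesian voxel grid (detection axis = `z`). Used to build
#' the overall PSF for the stripe-phantom benchmark.
#'
#' @param config An [optical_config()].
#' @param dims Integer vector `c(nx, ny, nz)` (odd values recommended).
#' @param voxel_nm Isotropic voxel size (nm).
#' @param n_theta Aperture-angle quadrature nodes.
#' @return A 3D array normalized to unit sum, with the voxel size attached
#'   as attribute `"voxel_nm"`.
#' @export
detection_psf_volume <- function(config, dims = c(33L, 33L, 121L),
                                 voxel_nm = 0.10 * config$lambda_exc /
                                   config$n_medium,
                                 n_theta = 256L) {
  stopifnot(length(dims) == 3L)
  k_det <- 2 * pi * config$n_medium / config$lambda_det
  th_max <- asin(config$NA_det / config$n_medium)
  # Gauss-Legendre nodes on [0, th_max]
  gl <- gauss_legendre(n_theta, 0, th_max)
  ax <- lapply(dims, function(n) (seq_len(n) - (n + 1) / 2) * voxel_nm)
  rho <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, `+`))
  rho_v <- as.vector(rho)
  J <- besselJ(outer(rho_v, k_det * sin(gl$x)), 0)        # (nx*ny) x ntheta
  wsin <- gl$w * sin(gl$x)
  phase <- exp(1i * k_det * outer(cos(gl$x), ax[[3]]))    # ntheta x nz
  A <- J %*% (phase * wsin)                               # (nx*ny) x nz
  psf <- array(Mod(A)^2, dim = dims)
  psf <- psf / sum(psf)
  attr(psf, "voxel_nm") <- voxel_nm
  psf
}

#' @keywords internal
gauss_legendre <- function(n, a, b) {
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

#' Overall swept OTF
#'
#' The overall transfer function of a swept light sheet is the 1D
#' convolution, along `kz` and at each `kx`, of the detection OTF slice with
#' the sheet's axial excitation OTF at the chosen propagation distance,
#' DC-normalized. The axial excitation harmonics create shifted copies of
#' the detection OTF that fill (or fail to fill) its missing cone.
#'
#' @param sheet A [swept_sheet()].
#' @param det A [detection_otf()] on the same grid.
#' @param y Propagation offset (nm); must be one of the sheet's planes.
#' @return An [otf_map] (complex values, rows `kz`, columns `kx`, DC = 1).
#' @export
overall_swept_otf <- function(sheet, det, y = 0) {
  stopifnot(inherits(sheet, "swept_sheet"), inherits(det, "detection_otf"))
  if (ncol(sheet$axial_otf) != nrow(det$slice_values))
    stop("sheet and detection OTF grids do not match", call. = FALSE)
  i <- sheet_plane_index(sheet, y)
  o <- sheet$axial_otf[i, ]
  N <- length(o)
  ctr <- (N + 1L) %/% 2L
  of <- stats::fft(ifftshift_vec(o))
  m <- (N - 1L) %/% 2L
  idx_in <- c((m + 1L):N, 1L:m)
  idx_out <- c((N - m + 1L):N, 1L:(N - m))
  Din <- det$slice_values[idx_in, , drop = FALSE]
  C <- stats::mvfft(stats::mvfft(Din) * of, inverse = TRUE) / N
  C <- C[idx_out, , drop = FALSE]
  C <- C / C[ctr, ctr]
  structure(list(values = C, y_offset = y, na_axis = sheet$kz_na,
                 normalization = "DC"),
            class = "otf_map")
}

#' Overall swept PSF volume
#'
#' Product of the detection PSF with the swept sheet's axial intensity
#' profile at propagation plane `y`: the sheet is uniform along the sweep
#' axis and varies negligibly along `y` over the extent of the detection
#' PSF, so `PSF_overall(x, y', z) = PSF_det(x, y', z) * I_sheet(y, z)`.
#' Normalized to unit sum.
#'
#' @param sheet A [swept_sheet()].
#' @param det_psf A [detection_psf_volume()] (3D array with voxel size).
#' @param y Propagation offset (nm).
#' @return A 3D array of class like the input, unit sum, voxel size kept.
#' @export
overall_psf <- function(sheet, det_psf, y = 0) {
  voxel <- attr(det_psf, "voxel_nm")
  if (is.null(voxel))
    stop("det_psf must carry a voxel_nm attribute (see ",
         "detection_psf_volume)", call. = FALSE)
  nz <- dim(det_psf)[3]
  z_ax <- (seq_len(nz) - (nz + 1) / 2) * voxel
  prof <- sheet_profile_at(sheet, y, z_ax)
  out <- sweep(det_psf, 3, prof, `*`)
  s <- sum(out)
  if (s <= 0) stop("overall PSF has zero total intensity", call. = FALSE)
  out <- out / s
  attr(out, "voxel_nm") <- voxel
  out
}

#' Structured-illumination support radii for a lattice light sheet
#'
#' In the coherent SIM mode the lattice's lateral harmonics extend the
#' lateral support by the largest `kx` harmonic of the excitation pattern
#' (`sqrt(3) k_o NA_exc` for hexagonal, `2 k_o NA_exc` for square lattices),
#' while the maximum axial support equals the swept-mode value. The
#' aperiodic hexrect pattern cannot be used for coherent SIM.
#'
#' @param symmetry `"axial_sw"`, `"square"` or `"hexagonal"` (`"hexrect"`
#'   errors).
#' @param NA_exc Lattice ring NA.
#' @param config An [optical_config()].
#' @param NA_exc_max Effective maximum excitation NA (defaults to `NA_exc`)
#'   used for the axial value.
#' @return A tibble with the lateral SIM support (cycles/nm), the lateral
#'   SIM resolution (nm) and the swept-equal axial resolution (nm).
#' @export
sim_support <- function(symmetry, NA_exc, config, NA_exc_max = NA_exc) {
  symmetry <- match.arg(symmetry,
                        c("axial_sw", "square", "hexagonal", "hexrect"))
  if (symmetry == "hexrect")
    stop("the hexrect pattern is aperiodic and cannot be applied to ",
         "coherent SIM", call. = FALSE)
  kx_harm <- switch(symmetry,
                    axial_sw = 0,
                    square = 2 * NA_exc / config$lambda_exc,
                    hexagonal = sqrt(3) * NA_exc / config$lambda_exc)
  lat <- 2 * config$NA_det / config$lambda_det + kx_harm
  bowtie <- (config$n_medium -
               sqrt(config$n_medium^2 - config$NA_det^2)) / config$lambda_det
  tibble::tibble(symmetry = symmetry, NA_exc = NA_exc,
                 lateral_support = lat,
                 R_x_SIM = 1 / lat,
                 R_z_max = 1 / (2 * NA_exc_max / config$lambda_exc + bowtie))
}
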