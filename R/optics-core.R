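#' Physical configuration of the light-sheet microscope
#'
#' Collects the constants that define the optical frame: the excitation and
#' detection (emission) vacuum wavelengths, the refractive index of the
#' imaging medium, the detection numerical aperture, the maximum NA the
#' excitation objective can pass, and the tilt of the objective pair with
#' respect to the specimen substrate. The coordinate convention throughout
#' the package is: `z` the sheet-confinement / detection axis, `y` the
#' propagation axis, and `x` the sweep axis. Pupil coordinates are expressed
#' in NA units, so transverse wave numbers are `k = k_o * NA` with
#' `k_o = 2*pi/lambda_exc`.
#'
#' @param lambda_exc Excitation vacuum wavelength (nm).
#' @param lambda_det Detection (emission) vacuum wavelength (nm).
#' @param n_medium Refractive index of the imaging medium.
#' @param NA_det Detection numerical aperture; must be below `n_medium`.
#' @param NA_exc_obj Maximum NA accepted by the excitation objective.
#' @param tilt_alpha Tilt of the objective axes relative to the specimen
#'   substrate, degrees in `[0, 90)`.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' cfg$lambda_exc / cfg$n_medium  # one medium wavelength in nm
#' @export
optical_config <- function(lambda_exc = 488, lambda_det = 520,
                           n_medium = 1.33, NA_det = 1.0,
                           NA_exc_obj = 0.60, tilt_alpha = 32.45) {
  stopifnot(is.numeric(lambda_exc), length(lambda_exc) == 1L,
            is.numeric(lambda_det), length(lambda_det) == 1L)
  if (lambda_exc <= 0 || lambda_det <= 0)
    stop("wavelengths must be positive", call. = FALSE)
  if (!(NA_det > 0 && NA_det < n_medium))
    stop("NA_det must satisfy 0 < NA_det < n_medium", call. = FALSE)
  if (!(NA_exc_obj > 0 && NA_exc_obj < n_medium))
    stop("NA_exc_obj must satisfy 0 < NA_exc_obj < n_medium", call. = FALSE)
  if (tilt_alpha < 0 || tilt_alpha >= 90)
    stop("tilt_alpha must lie in [0, 90) degrees", call. = FALSE)
  structure(
    list(lambda_exc = lambda_exc, lambda_det = lambda_det,
         n_medium = n_medium, NA_det = NA_det, NA_exc_obj = NA_exc_obj,
         tilt_alpha = tilt_alpha),
    class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  lambda_exc = %g nm, lambda_det = %g nm, n = %g\n",
              x$lambda_exc, x$lambda_det, x$n_medium))
  cat(sprintf("  NA_det = %g, NA_exc_obj = %g, tilt = %g deg\n",
              x$NA_det, x$NA_exc_obj, x$tilt_alpha))
  invisible(x)
}

# excitation vacuum wavenumber k_o = 2*pi/lambda_exc (rad/nm)
#' @keywords internal
k_o <- function(config) 2 * pi / config$lambda_exc

#' Conjugate pupil / focal sampling grids
#'
#' Builds the pair of centered sampling grids used by every simulation: a
#' pupil grid in NA units with spacing `dNA = NA_span / N_k` and the
#' conjugate focal-plane grid with spacing `dx = lambda_exc / (N_k * dNA)`,
#' so that `dx * dNA * N_k = lambda_exc` holds per axis (discrete Fourier
#' transform pair consistency). Grids are odd-sized so the zero frequency
#' and the focal origin are exact samples.
#'
#' @param config An [optical_config()].
#' @param NA_span Full extent of the pupil grid in NA units. Must cover at
#'   least `2 * max(NA_exc_obj, NA_det) * 1.1` so transfer-function supports
#'   fit, and at most `2 * n_medium` (beyond which samples are evanescent
#'   only). The default, 4 NA units, Nyquist-resolves the lateral support of
#'   a detection OTF up to `NA_det = 1.0` at 488/520 nm.
#' @param N_k Number of pupil samples per axis; must be odd.
#' @param y_extent Full extent of the propagation-offset list (nm).
#' @param n_y Number of propagation planes; planes are symmetric about 0.
#'
#' @return An object of class `grid_set` with fields `N_k`, `dNA`,
#'   `na_axis`, `dx`, `x_axis`, `y_planes`.
#' @examples
#' g <- make_grids(optical_config(), NA_span = 4, N_k = 501)
#' g$dx * g$dNA * g$N_k   # = lambda_exc
#' @export
make_grids <- function(config, NA_span = 4.0, N_k = 1001,
                       y_extent = 0, n_y = 1) {
  stopifnot(inherits(config, "optical_config"))
  N_k <- as.integer(N_k)
  if (N_k %% 2L == 0L)
    stop("N_k must be odd so that the zero frequency is an exact sample",
         call. = FALSE)
  if (NA_span > 4 * config$n_medium)
    stop("NA_span exceeds 4*n_medium: the pupil can carry no content ",
         "beyond NA = n, and no transfer function reaches beyond twice ",
         "that, so the extra span would be pure padding", call. = FALSE)
  if (NA_span < 2 * max(config$NA_exc_obj, config$NA_det) * 1.1)
    stop("NA_span too small: need at least 2*max(NA_exc_obj, NA_det)*1.1 ",
         "to contain the transfer-function supports", call. = FALSE)
  dNA <- NA_span / N_k
  dx <- config$lambda_exc / (N_k * dNA)
  half <- (N_k - 1L) %/% 2L
  idx <- seq.int(-half, half)
  y_planes <- if (y_extent <= 0 || n_y <= 1L) 0
  else seq(-y_extent / 2, y_extent / 2, length.out = n_y)
  structure(
    list(N_k = N_k, dNA = dNA, na_axis = idx * dNA,
         dx = dx, x_axis = idx * dx, y_planes = y_planes,
         NA_span = NA_span, config = config),
    class = "grid_set")
}

#' @export
print.grid_set <- function(x, ...) {
  cat("<grid_set>\n")
  cat(sprintf("  N_k = %d, dNA = %.5f NA, dx = %.2f nm (extent %.1f um)\n",
              x$N_k, x$dNA, x$dx, x$N_k * x$dx / 1e3))
  cat(sprintf("  y planes: %d in [%.0f, %.0f] nm\n", length(x$y_planes),
              min(x$y_planes), max(x$y_planes)))
  invisible(x)
}

# axial wavenumber map ky(kx, kz) = sqrt((n k_o)^2 - kx^2 - kz^2) on the
# pupil grid, in rad/nm; NA (not zero) outside the propagating circle.
#' @keywords internal
ky_map <- function(grids) {
  cfg <- grids$config
  ko <- k_o(cfg)
  na2 <- outer(grids$na_axis^2, grids$na_axis^2, `+`) # rows kz, cols kx
  arg <- (cfg$n_medium * ko)^2 - na2 * ko^2
  ky <- sqrt(pmax(arg, 0))
  ky[arg < 0] <- NA_real_
  ky
}

#' Construct a pupil field object
#'
#' Low-level constructor wrapping a complex matrix sampled on the pupil
#' grid (rows index `NA_z`, columns `NA_x`). Most users will call one of
#' the sheet-family synthesizers instead ([gaussian_pupil()],
#' [sinc_pupil()], [bessel_pupil()], [mb_pupil()], [ac_pupil()],
#' [hb_design()]).
#'
#' @param values Complex (or numeric) matrix of size `N_k x N_k`.
#' @param grids A [make_grids()] grid set.
#' @param spec Optional originating [sheet_spec()].
#' @param beamlets Optional tibble of beamlet annotations.
#' @return An object of class `pupil_field`.
#' @export
pupil_field <- function(values, grids, spec = NULL, beamlets = NULL) {
  stopifnot(inherits(grids, "grid_set"))
  if (!is.matrix(values) || nrow(values) != grids$N_k ||
      ncol(values) != grids$N_k)
    stop("pupil values must be an N_k x N_k matrix", call. = FALSE)
  storage.mode(values) <- "complex"
  structure(list(values = values, grids = grids, spec = spec,
                 beamlets = beamlets),
            class = "pupil_field")
}

#' @export
print.pupil_field <- function(x, ...) {
  nz <- sum(Mod(x$values) > 0)
  cat(sprintf("<pupil_field> %d x %d grid, %d nonzero samples",
              nrow(x$values), ncol(x$values), nz))
  if (!is.null(x$spec)) cat(sprintf(", family '%s'", x$spec$family))
  cat("\n")
  invisible(x)
}

# error if the pupil has support outside the propagating circle NA_rho = n
#' @keywords internal
check_propagating <- function(pupil, grids) {
  cfg <- grids$config
  rho <- sqrt(outer(grids$na_axis^2, grids$na_axis^2, `+`))
  bad <- Mod(pupil) > 0 & rho > cfg$n_medium
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    stop(sprintf(paste0("pupil has %d nonzero samples outside the ",
                        "propagating circle NA = n = %g (first at NA_z = ",
                        "%.3f, NA_x = %.3f); evanescent content indicates ",
                        "a configuration error"),
                 nrow(idx), cfg$n_medium,
                 grids$na_axis[idx[1, 1]], grids$na_axis[idx[1, 2]]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Propagate a pupil field to a focal-plane field
#'
#' Evaluates the scalar angular-spectrum integral: the field at the specimen
#' is the inverse 2D Fourier transform of the pupil field multiplied by the
#' defocus propagator `exp(i * ky * y)`, with
#' `ky = sqrt((n k_o)^2 - kx^2 - kz^2)`. At `y = 0` the propagator is the
#' identity. The transform is unitary, so the integrated power of the focal
#' field equals that of the pupil field for every `y`.
#'
#' @param pupil A [pupil_field()] (or bare complex matrix).
#' @param grids The [make_grids()] grid set the pupil is sampled on.
#' @param y Propagation offset from the excitation focal plane (nm).
#' @return An object of class `focal_field` with fields `values` (complex
#'   matrix, rows `z`, columns `x`), `y_offset`, `x_axis`, `z_axis`.
#' @examples
#' cfg <- optical_config()
#' g <- make_grids(cfg, N_k = 315)
#' pup <- bessel_pupil(sheet_spec("bessel", NA_min = 0.4, NA_max = 0.47), g)
#' foc <- pupil_to_focal(pup, g, y = 0)
#' sum(Mod(foc$values)^2) - sum(Mod(pup$values)^2)  # Parseval: ~0
#' @export
pupil_to_focal <- function(pupil, grids, y = 0) {
  P <- if (inherits(pupil, "pupil_field")) pupil$values else pupil
  stopifnot(inherits(grids, "grid_set"))
  check_propagating(P, grids)
  ky <- ky_map(grids)
  prop <- exp(1i * ky * y)
  prop[is.na(ky)] <- 0
  E <- ifft2c(P * prop)
  structure(list(values = E, y_offset = y,
                 x_axis = grids$x_axis, z_axis = grids$x_axis),
            class = "focal_field")
}

#' @export
print.focal_field <- function(x, ...) {
  cat(sprintf("<focal_field> %d x %d at y = %.0f nm, peak |E| = %.3g\n",
              nrow(x$values), ncol(x$values), x$y_offset,
              max(Mod(x$values))))
  invisible(x)
}

# Sheet on-axis intensity I(y, z = 0), swept over x, for a vector of
# propagation offsets. Uses the column-collapse identity
#   mean_x |E(x, 0; y)|^2 = (1/N^2) * sum_kx | sum_kz P * exp(i ky y) |^2,
# which avoids the full 2D transform per plane.
#' @keywords internal
on_axis_profile <- function(pupil, grids, y_values) {
  P <- if (inherits(pupil, "pupil_field")) pupil$values else pupil
  check_propagating(P, grids)
  ky <- ky_map(grids)
  ky[is.na(ky)] <- 0
  N <- grids$N_k
  nz <- which(colSums(Mod(P)) > 0)   # skip empty pupil columns
  P <- P[, nz, drop = FALSE]
  ky <- ky[, nz, drop = FALSE]
  vapply(y_values, function(y) {
    cs <- colSums(P * exp(1i * ky * y))
    sum(Mod(cs)^2) / N^2
  }, numeric(1))
}
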