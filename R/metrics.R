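# full width at half maximum of a sampled profile by linear interpolation
#' @keywords internal
fwhm_of_profile <- function(x, I, what = "profile") {
  ipk <- which.max(I)
  half <- I[ipk] / 2
  n <- length(I)
  right <- NA_real_
  for (j in seq.int(ipk, n - 1L)) {
    if (I[j + 1L] <= half && I[j] > half) {
      right <- x[j] + (x[j + 1L] - x[j]) * (I[j] - half) / (I[j] - I[j + 1L])
      break
    }
  }
  left <- NA_real_
  for (j in seq.int(ipk, 2L)) {
    if (I[j - 1L] <= half && I[j] > half) {
      left <- x[j] - (x[j] - x[j - 1L]) * (I[j] - half) / (I[j] - I[j - 1L])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop(what, " does not drop below half maximum within the sampled range",
         call. = FALSE)
  right - left
}

#' Propagation length of a swept sheet
#'
#' Full width at half maximum of the on-axis swept intensity `I(y, z = 0)`
#' along the propagation direction, by linear interpolation between the
#' sampled planes.
#'
#' @param sheet A [swept_sheet()] sampled over a symmetric range of `y`
#'   planes wide enough that the profile drops below half maximum.
#' @return The propagation length `y_FWHM` in nm.
#' @export
y_fwhm <- function(sheet) {
  stopifnot(inherits(sheet, "swept_sheet"))
  if (length(sheet$y_planes) < 5L)
    stop("sheet must be sampled over several y planes to measure y_FWHM",
         call. = FALSE)
  ctr <- (ncol(sheet$intensity) + 1L) %/% 2L
  fwhm_of_profile(sheet$y_planes, sheet$intensity[, ctr],
                  what = "on-axis intensity I(y, 0)")
}

#' Propagation length measured directly from a pupil
#'
#' Convenience variant of [y_fwhm()] that evaluates the on-axis swept
#' intensity `I(y, 0)` by a fast column-collapse sum (no full 2D transforms)
#' on a dense symmetric `y` grid.
#'
#' @param pupil A [pupil_field()].
#' @param grids A [make_grids()] grid set.
#' @param y_max Half-range of the scan (nm).
#' @param n_y Number of planes across `[-y_max, y_max]` (odd recommended).
#' @return `y_FWHM` in nm.
#' @export
y_fwhm_pupil <- function(pupil, grids, y_max, n_y = 161L) {
  yv <- seq(-y_max, y_max, length.out = n_y)
  I <- on_axis_profile(pupil, grids, yv)
  fwhm_of_profile(yv, I, what = "on-axis intensity I(y, 0)")
}

#' Propagation length of a single pupil beamlet
#'
#' Closed-form propagation length of a beamlet occupying radial numerical
#' apertures `NA_minus` to `NA_plus`:
#' `lambda_exc / (2 n (sqrt(1 - (NA_minus/n)^2) - sqrt(1 - (NA_plus/n)^2)))`,
#' i.e. `pi` over the spread in axial wavenumber `ky` across the beamlet.
#' Strictly decreasing in `NA_plus` and increasing in `NA_minus`: beamlets
#' spanning the same radial range share the same length regardless of where
#' they sit on the ring.
#'
#' @param NA_minus,NA_plus Radial NA bounds, `0 <= NA_minus < NA_plus < n`.
#' @param config An [optical_config()].
#' @return Length in nm (vectorized over the bounds).
#' @export
beamlet_length <- function(NA_minus, NA_plus, config) {
  n <- config$n_medium
  if (any(NA_minus < 0) || any(NA_plus >= n) || any(NA_minus >= NA_plus))
    stop("need 0 <= NA_minus < NA_plus < n_medium", call. = FALSE)
  dky <- sqrt(1 - (NA_minus / n)^2) - sqrt(1 - (NA_plus / n)^2)
  config$lambda_exc / (2 * n * dky)
}

#' Widefield axial resolution limit
#'
#' Maximum axial resolution of a widefield microscope of the given NA:
#' `lambda_det / (n - sqrt(n^2 - NA^2))`, the reciprocal of the detection
#' OTF's maximum axial (bowtie) extent.
#'
#' @param na Numerical aperture (must be below `n`).
#' @param lambda_det Emission wavelength (nm).
#' @param n Medium refractive index.
#' @return Resolution in nm.
#' @export
widefield_axial_resolution <- function(na, lambda_det, n) {
  if (any(na >= n)) stop("NA must be below the medium index", call. = FALSE)
  lambda_det / (n - sqrt(n^2 - na^2))
}

#' OTF gap / discontinuity criterion
#'
#' For an axial standing wave or swept square lattice, the shifted copies of
#' the detection OTF separate completely from the DC copy -- the overall
#' swept OTF becomes discontinuous -- once the harmonic shift
#' `2 k_o NA_exc` exceeds the maximum axial width of the detection bowtie.
#' The threshold ring NA is
#' `NA* = (lambda_exc / lambda_det) (n - sqrt(n^2 - NA_det^2))`.
#'
#' @param NA_exc Lattice ring NA to test.
#' @param config An [optical_config()].
#' @return A list with `threshold` (NA units) and `discontinuous` (logical).
#' @export
gap_criterion <- function(NA_exc, config) {
  thr <- (config$lambda_exc / config$lambda_det) *
    (config$n_medium - sqrt(config$n_medium^2 - config$NA_det^2))
  list(threshold = thr, discontinuous = NA_exc > thr)
}

#' Theoretical resolution limits of a swept light sheet
#'
#' Closed-form support-radius resolutions for a light sheet of effective
#' maximum excitation NA `NA_exc_max` under the configured detection optics:
#'
#' * `R_x_swept = lambda_det / (2 NA_det)` -- lateral, set by detection
#'   alone in the swept mode;
#' * `R_z_axis = lambda_exc / (2 NA_exc_max)` -- axial along the detection
#'   axis (`kx = 0`), set by the excitation harmonics alone (the detection
#'   OTF contributes nothing there because of its missing cone);
#' * `R_z_max = 1 / (2 NA_exc_max / lambda_exc + (n - sqrt(n^2 -
#'   NA_det^2)) / lambda_det)` -- the best axial resolution, attained at the
#'   lateral offset where the detection bowtie is widest;
#' * `R_x_SIM` -- lateral resolution in the coherent SIM mode (only for
#'   square/hexagonal symmetry; see [sim_support()]).
#'
#' Specimen-frame values are obtained by rotating the support by the
#' objective tilt `alpha` and scanning the boundary numerically; they are
#' computed when an overall [otf_map] is supplied.
#'
#' @param config An [optical_config()].
#' @param NA_exc_max Effective maximum excitation NA (for Gaussian-beamlet
#'   lattices: `min(NA_exc + sigma_ref, annulus NA_max)`).
#' @param symmetry Optional lattice symmetry for the SIM lateral value.
#' @param NA_exc Ring NA used for the SIM harmonics (defaults to
#'   `NA_exc_max`).
#' @param otf Optional overall swept [otf_map] from which specimen-frame
#'   support radii are measured numerically.
#' @param support_threshold Relative modulus threshold defining the numeric
#'   support when `otf` is given.
#' @return A one-row tibble of class `resolution_report`.
#' @export
resolution_limits <- function(config, NA_exc_max, symmetry = NULL,
                              NA_exc = NA_exc_max, otf = NULL,
                              support_threshold = 1e-3) {
  if (NA_exc_max > config$NA_exc_obj + 1e-9)
    stop("NA_exc_max exceeds the excitation objective NA", call. = FALSE)
  lam_e <- config$lambda_exc; lam_d <- config$lambda_det
  n <- config$n_medium
  bowtie <- (n - sqrt(n^2 - config$NA_det^2)) / lam_d
  R_x_swept <- lam_d / (2 * config$NA_det)
  R_z_axis <- lam_e / (2 * NA_exc_max)
  R_z_max <- 1 / (2 * NA_exc_max / lam_e + bowtie)
  R_x_SIM <- if (!is.null(symmetry) &&
                 symmetry %in% c("square", "hexagonal"))
    sim_support(symmetry, NA_exc, config, NA_exc_max)$R_x_SIM
  else NA_real_
  R_x_spec <- R_z_spec <- NA_real_
  if (!is.null(otf)) {
    pr <- specimen_projection(otf, config$tilt_alpha,
                              lambda_exc = lam_e,
                              support_threshold = support_threshold)
    R_x_spec <- pr[["R_x_specimen"]]
    R_z_spec <- pr[["R_z_specimen"]]
  }
  out <- tibble::tibble(
    NA_exc_max = NA_exc_max,
    R_x_swept = R_x_swept, R_z_axis = R_z_axis, R_z_max = R_z_max,
    R_x_SIM = R_x_SIM,
    R_x_specimen = R_x_spec, R_z_specimen = R_z_spec)
  class(out) <- c("resolution_report", class(out))
  out
}

#' Specimen-frame projection of a support boundary
#'
#' The excitation and detection objectives are tilted by `alpha` relative to
#' the specimen substrate in the `xz` plane, so resolutions along the
#' specimen axes are set by the support radius along the rotated directions
#' `e_x_spec = cos(a) e_x + sin(a) e_z` and `e_z_spec = -sin(a) e_x +
#' cos(a) e_z`. The radius is found by a dense scan along each ray through
#' the numerically thresholded support.
#'
#' @param support An [otf_map] (its modulus is thresholded), or a list with
#'   fields `mask` (logical matrix, rows `kz`, columns `kx`), `fx`, `fz`
#'   (axes in cycles/nm).
#' @param tilt_alpha Tilt angle in degrees.
#' @param lambda_exc Needed to convert an `otf_map`'s NA-unit axes to
#'   cycles/nm.
#' @param support_threshold Relative modulus threshold for an `otf_map`.
#' @param n_t Samples along each ray.
#' @return Named numeric vector `R_x_specimen`, `R_z_specimen` (nm).
#' @export
specimen_projection <- function(support, tilt_alpha, lambda_exc = NULL,
                                support_threshold = 1e-3, n_t = 2048L) {
  if (inherits(support, "otf_map")) {
    if (is.null(lambda_exc))
      stop("lambda_exc needed to convert NA-unit axes to cycles/nm",
           call. = FALSE)
    f <- support$na_axis / lambda_exc
    support <- list(mask = Mod(support$values) >
                      support_threshold * max(Mod(support$values)),
                    fz = f, fx = f)
  }
  a <- tilt_alpha * pi / 180
  dfz <- support$fz[2] - support$fz[1]
  dfx <- support$fx[2] - support$fx[1]
  cz <- which.min(abs(support$fz))
  cx <- which.min(abs(support$fx))
  radius_along <- function(ux, uz) {
    tmax <- min(max(abs(support$fx)) / max(abs(ux), 1e-12),
                max(abs(support$fz)) / max(abs(uz), 1e-12))
    tv <- seq(0, tmax, length.out = n_t)
    iz <- pmin(pmax(round(tv * uz / dfz) + cz, 1L), length(support$fz))
    ix <- pmin(pmax(round(tv * ux / dfx) + cx, 1L), length(support$fx))
    inside <- support$mask[cbind(iz, ix)]
    if (!any(inside)) return(NA_real_)
    tv[max(which(inside))]
  }
  r_x <- radius_along(cos(a), sin(a))
  r_z <- radius_along(-sin(a), cos(a))
  c(R_x_specimen = 1 / r_x, R_z_specimen = 1 / r_z)
}

#' Cumulative axial confinement of a swept sheet
#'
#' Fraction of the swept excitation intensity within `|z'| <= z` of the
#' sheet center at propagation plane `y`, normalized to the integral across
#' the entire profile: a direct measure of how much of the excitation (and
#' hence photobleaching) budget lies in the central peak versus sidelobes.
#'
#' @param sheet A [swept_sheet()].
#' @param y Propagation plane (nm).
#' @return A tibble of class `confinement_curve` with columns `z_nm`
#'   (nonnegative half-widths) and `cumulative` (monotone, reaching 1).
#' @export
cumulative_intensity <- function(sheet, y = 0) {
  i <- sheet_plane_index(sheet, y)
  I <- sheet$intensity[i, ]
  tot <- sum(I)
  if (tot <= 0) stop("sheet profile has zero total intensity", call. = FALSE)
  z <- sheet$z_axis
  ctr <- (length(z) + 1L) %/% 2L
  half_z <- z[ctr:length(z)] - z[ctr]
  # trapezoidal integral of I over [-z, z] about the center sample, so the
  # curve matches the continuum integral rather than a step sum
  right <- I[ctr:length(I)]
  left <- I[ctr:1]
  m <- min(length(right), length(left))
  both <- right[seq_len(m)] + left[seq_len(m)]
  run <- cumsum(both) - both / 2 - both[1] / 2
  tot_trap <- sum(I) - I[1] / 2 - I[length(I)] / 2
  cum <- pmin(run[seq_along(half_z)] / tot_trap, 1)
  out <- tibble::tibble(z_nm = half_z, cumulative = cum)
  class(out) <- c("confinement_curve", class(out))
  out
}

#' Linecuts through an OTF map
#'
#' Extracts the three standard diagnostic cuts through an overall OTF: the
#' modulus along `kx = 0` (axial cut through the missing cone), along
#' `kz = 0` (lateral cut), and along the vertical line at half the lateral
#' detection support, `kx = NA_det * lambda_exc / lambda_det` in NA units,
#' where the widefield microscope attains its best axial resolution.
#'
#' @param otf An [otf_map].
#' @param config An [optical_config()] (fixes the half-support line); or
#'   pass `kx_half` directly.
#' @param kx_half Lateral offset of the third cut in NA units.
#' @return A tibble with columns `cut`, `k_na`, `modulus`.
#' @export
otf_linecuts <- function(otf, config = NULL, kx_half = NULL) {
  stopifnot(inherits(otf, "otf_map"))
  kx_half <- kx_half %||% {
    if (is.null(config))
      stop("supply either config or kx_half", call. = FALSE)
    config$NA_det * config$lambda_exc / config$lambda_det
  }
  ax <- otf$na_axis
  ctr <- (length(ax) + 1L) %/% 2L
  j <- which.min(abs(ax - kx_half))
  tibble::tibble(
    cut = rep(c("kx=0", "kz=0", "kx=half-lateral-support"),
              each = length(ax)),
    k_na = c(ax, ax, ax),
    modulus = c(Mod(otf$values[, ctr]), Mod(otf$values[ctr, ]),
                Mod(otf$values[, j])))
}

# maximum |kz| of the numeric support of an overall OTF (cycles/nm), used to
# cross-check R_z_max against the measured support
#' @keywords internal
measured_axial_support <- function(otf, lambda_exc, threshold = 1e-3) {
  mask <- Mod(otf$values) > threshold * max(Mod(otf$values))
  kz_na <- otf$na_axis[apply(mask, 1, any)]
  max(abs(kz_na)) / lambda_exc
}
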