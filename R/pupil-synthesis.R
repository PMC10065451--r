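#' Specification of a light-sheet family
#'
#' A `sheet_spec` names one of the seven light-sheet families and its
#' parameters:
#'
#' * `gaussian` -- a 1D Gaussian sheet of waist `w0` (nm), realized either as
#'   a single vertical pupil line or as two lines offset by `x_offset_NA`
#'   (standing-wave realization that clears the annular mask).
#' * `sinc` -- uniform pupil line(s) of half-bandwidth `NA_sinc`, giving a
#'   `sinc^2` axial profile at focus.
#' * `bessel` -- a uniform annulus from `NA_min` to `NA_max`.
#' * `mb` -- coherent multi-Bessel lattice: vertical uniform bands of period
#'   `2*pi/T` in `kx`, cropped by the annulus. At the symmetry-specific
#'   periods the pattern equals a bound 2D optical lattice.
#' * `ac` -- axially confined lattice: each ideal-lattice pupil point
#'   replaced by a Gaussian stripe of common 1/e amplitude half-width
#'   `sigma_NA` (NA units).
#' * `hb` -- harmonic-balanced lattice: per-beamlet stripe widths and
#'   amplitudes set so all swept-OTF harmonics have equal strength and equal
#'   propagation length (see [hb_design()]).
#' * `cs` -- cosine-sinc sheet: the band-by-band incoherent equivalent of an
#'   `mb` sheet (see [cs_profile()]).
#'
#' @param family One of `"gaussian"`, `"sinc"`, `"bessel"`, `"mb"`, `"ac"`,
#'   `"hb"`, `"cs"`.
#' @param symmetry Lattice symmetry: `"axial_sw"`, `"square"`,
#'   `"hexagonal"`, `"hexrect"` or `"none"`.
#' @param NA_exc Lattice ring NA (NA units).
#' @param NA_min,NA_max Annulus bounds (NA units), `0 <= NA_min < NA_max`.
#' @param w0 Gaussian waist (nm; `gaussian` family).
#' @param NA_sinc Sinc half-bandwidth (NA units; `sinc` family).
#' @param sigma_NA Beamlet 1/e amplitude (1/e^2 intensity) half-width in the
#'   pupil, NA units (`ac`/`hb` families).
#' @param epsilon SLM cropping factor in `[0, 1)` (see [phase_grayscale()]).
#' @param x_offset_NA Lateral pupil offset of the line beamlets used by the
#'   standing-wave realization of `gaussian`/`sinc` sheets.
#' @param T_override Optional lattice period override (nm; `mb` family).
#'
#' @return An object of class `sheet_spec`.
#' @export
sheet_spec <- function(family,
                       symmetry = "none",
                       NA_exc = NA_real_,
                       NA_min = NA_real_, NA_max = NA_real_,
                       w0 = NA_real_, NA_sinc = NA_real_,
                       sigma_NA = NA_real_, epsilon = 0,
                       x_offset_NA = 0, T_override = NULL) {
  family <- match.arg(family,
                      c("gaussian", "sinc", "bessel", "mb", "ac", "hb", "cs"))
  symmetry <- match.arg(symmetry,
                        c("none", "axial_sw", "square", "hexagonal", "hexrect"))
  if (epsilon < 0 || epsilon >= 1)
    stop("epsilon must lie in [0, 1)", call. = FALSE)
  if (!is.na(NA_min) && !is.na(NA_max) && !(NA_min >= 0 && NA_min < NA_max))
    stop("annulus requires 0 <= NA_min < NA_max", call. = FALSE)
  if (family %in% c("mb", "ac", "hb", "cs") && symmetry == "none" &&
      is.null(T_override))
    stop(sprintf("family '%s' requires a lattice symmetry", family),
         call. = FALSE)
  if (family %in% c("ac", "hb") && (is.na(sigma_NA) || sigma_NA <= 0))
    stop("sigma_NA > 0 required for ac/hb families", call. = FALSE)
  if (family == "gaussian" && (is.na(w0) || w0 <= 0))
    stop("gaussian family requires a positive waist w0 (nm)", call. = FALSE)
  if (family == "sinc" && (is.na(NA_sinc) || NA_sinc <= 0))
    stop("sinc family requires a positive NA_sinc", call. = FALSE)
  if (family %in% c("bessel", "mb", "cs") && (is.na(NA_min) || is.na(NA_max)))
    stop(sprintf("family '%s' requires annulus bounds NA_min/NA_max", family),
         call. = FALSE)
  structure(
    list(family = family, symmetry = symmetry, NA_exc = NA_exc,
         NA_min = NA_min, NA_max = NA_max, w0 = w0, NA_sinc = NA_sinc,
         sigma_NA = sigma_NA, epsilon = epsilon,
         x_offset_NA = x_offset_NA, T_override = T_override),
    class = "sheet_spec")
}

#' @export
print.sheet_spec <- function(x, ...) {
  cat(sprintf("<sheet_spec> family '%s', symmetry '%s'\n",
              x$family, x$symmetry))
  flds <- c("NA_exc", "NA_min", "NA_max", "w0", "NA_sinc", "sigma_NA",
            "epsilon", "x_offset_NA")
  for (f in flds)
    if (!is.na(x[[f]]) && !(f == "epsilon" && x[[f]] == 0) &&
        !(f == "x_offset_NA" && x[[f]] == 0))
      cat(sprintf("  %s = %g\n", f, x[[f]]))
  invisible(x)
}

#' Ideal-lattice plane-wave directions on the pupil ring
#'
#' Returns the pupil positions of the plane waves composing a maximally
#' symmetric 2D optical lattice of the requested symmetry, all lying on the
#' ring of radius `NA_exc`:
#'
#' * `axial_sw`: 2 polar points `(0, +/-NA_exc)`;
#' * `square`: the polar pair plus 2 equatorial points `(+/-NA_exc, 0)`;
#' * `hexagonal`: 6 points equally spaced azimuthally -- the polar pair and
#'   four flanking points at `NA_z = +/-NA_exc/2`;
#' * `hexrect`: the hexagonal set plus 8 more ring points at
#'   `NA_z = +/-NA_exc/4` and `+/-3*NA_exc/4` (14 points total), whose swept
#'   axial harmonics interleave the hexagonal ones to give nine equally
#'   spaced detection-OTF copies.
#'
#' @param symmetry One of `"axial_sw"`, `"square"`, `"hexagonal"`,
#'   `"hexrect"`.
#' @param NA_exc Ring radius in NA units.
#' @return A tibble with columns `na_x`, `na_z` (pupil position, NA units),
#'   `s_b`, `c_b` (lateral and axial direction cosines of the unit wave
#'   vector in the sheet cross-section), one row per plane wave.
#' @examples
#' lattice_wavevectors("hexagonal", 0.5)
#' @export
lattice_wavevectors <- function(symmetry, NA_exc) {
  symmetry <- match.arg(symmetry,
                        c("axial_sw", "square", "hexagonal", "hexrect"))
  stopifnot(NA_exc > 0)
  frac_z <- switch(symmetry,
    axial_sw  = c(1, -1),
    square    = c(1, -1, 0, 0),
    hexagonal = c(1, -1, 0.5, 0.5, -0.5, -0.5),
    hexrect   = c(1, -1, 0.5, 0.5, -0.5, -0.5,
                  0.25, 0.25, -0.25, -0.25, 0.75, 0.75, -0.75, -0.75))
  sign_x <- switch(symmetry,
    axial_sw  = c(0, 0),
    square    = c(0, 0, 1, -1),
    hexagonal = c(0, 0, 1, -1, 1, -1),
    hexrect   = c(0, 0, 1, -1, 1, -1, 1, -1, 1, -1, 1, -1, 1, -1))
  na_z <- frac_z * NA_exc
  na_x <- sign_x * sqrt(pmax(NA_exc^2 - na_z^2, 0))
  tibble::tibble(na_x = na_x, na_z = na_z,
                 s_b = na_x / NA_exc, c_b = na_z / NA_exc)
}

# nearest pupil-grid column/row index for an NA value
#' @keywords internal
na_index <- function(na, grids) {
  half <- (grids$N_k - 1L) %/% 2L
  i <- as.integer(round(na / grids$dNA)) + half + 1L
  if (any(i < 1L | i > grids$N_k))
    stop("NA coordinate falls outside the pupil grid", call. = FALSE)
  i
}

# truncate a stripe profile: drop amplitudes < tol * max and verify what is
# left stays inside the propagating circle (else error, per the evanescent
# hard-reject policy); optionally crop radially by an annulus.
#' @keywords internal
stripe_column <- function(grids, na_x_center, profile, tol = 1e-8,
                          NA_min = NA_real_, NA_max = NA_real_,
                          what = "stripe") {
  keep <- Mod(profile) > tol * max(Mod(profile))
  rho <- sqrt(na_x_center^2 + grids$na_axis^2)
  if (any(keep & rho > grids$config$n_medium))
    stop(sprintf("%s extends past the propagating circle NA = n = %g",
                 what, grids$config$n_medium), call. = FALSE)
  if (!is.na(NA_min) && !is.na(NA_max))
    keep <- keep & rho >= NA_min & rho <= NA_max
  profile[!keep] <- 0
  profile
}

#' Gaussian light-sheet pupil
#'
#' Builds the pupil field of a 1D Gaussian light sheet: one (or, in the
#' standing-wave realization, two) vertical excitation line(s) with axial
#' profile `exp(-(kz * w0)^2 / 4)`, the Fourier transform of the focal
#' amplitude `exp(-(z/w0)^2)`. With `x_offset_NA = 0` the single ideal line
#' is returned; with a nonzero offset two lines at `+/-x_offset_NA` create a
#' lateral standing wave bound in `z` by the same Gaussian envelope, whose
#' swept excitation PSF is identical to the 1D sheet's.
#'
#' @param spec A [sheet_spec()] with `family = "gaussian"`.
#' @param grids A [make_grids()] grid set.
#' @return A [pupil_field()].
#' @export
gaussian_pupil <- function(spec, grids) {
  stopifnot(inherits(spec, "sheet_spec"), spec$family == "gaussian")
  ko <- k_o(grids$config)
  kz <- ko * grids$na_axis
  prof <- exp(-0.25 * (kz * spec$w0)^2)
  if (!is.na(spec$NA_min) && spec$NA_min > 0 &&
      spec$x_offset_NA <= spec$NA_min)
    warning("x_offset_NA <= NA_min: the annular mask will clip the ",
            "excitation line", call. = FALSE)
  offs <- if (spec$x_offset_NA == 0) 0 else c(-1, 1) * spec$x_offset_NA
  vals <- matrix(0 + 0i, grids$N_k, grids$N_k)
  for (o in offs) {
    col <- stripe_column(grids, o, prof, what = "Gaussian pupil line")
    vals[, na_index(o, grids)] <- vals[, na_index(o, grids)] + col
  }
  pupil_field(vals, grids, spec = spec)
}

#' Sinc light-sheet pupil
#'
#' Uniform vertical pupil line(s) truncated at `|NA_z| = NA_sinc`, the
#' pupil of a sheet with `sinc^2(k_o * NA_sinc * z)` axial intensity at
#' focus. The swept axial excitation OTF at focus is the triangle function
#' `tri(kz / (2 k_o NA_sinc))`. As for the Gaussian sheet, a nonzero
#' `x_offset_NA` gives the two-line standing-wave realization.
#'
#' @inheritParams gaussian_pupil
#' @return A [pupil_field()].
#' @export
sinc_pupil <- function(spec, grids) {
  stopifnot(inherits(spec, "sheet_spec"), spec$family == "sinc")
  if (spec$NA_sinc > grids$config$NA_exc_obj)
    stop("NA_sinc exceeds the excitation objective NA", call. = FALSE)
  prof <- as.numeric(abs(grids$na_axis) <= spec$NA_sinc) + 0i
  if (!is.na(spec$NA_min) && spec$NA_min > 0 &&
      spec$x_offset_NA <= spec$NA_min)
    warning("x_offset_NA <= NA_min: the annular mask will clip the ",
            "excitation line", call. = FALSE)
  offs <- if (spec$x_offset_NA == 0) 0 else c(-1, 1) * spec$x_offset_NA
  vals <- matrix(0 + 0i, grids$N_k, grids$N_k)
  for (o in offs) vals[, na_index(o, grids)] <- prof
  pupil_field(vals, grids, spec = spec)
}

#' Bessel-beam annulus pupil
#'
#' Constant complex amplitude on the annulus `NA_min <= NA_rho <= NA_max`,
#' zero elsewhere: the pupil of a radially bound Bessel-like beam.
#'
#' @inheritParams gaussian_pupil
#' @return A [pupil_field()].
#' @export
bessel_pupil <- function(spec, grids) {
  stopifnot(inherits(spec, "sheet_spec"), spec$family == "bessel")
  rho <- sqrt(outer(grids$na_axis^2, grids$na_axis^2, `+`))
  vals <- matrix(0 + 0i, grids$N_k, grids$N_k)
  sel <- rho >= spec$NA_min & rho <= spec$NA_max
  if (!any(sel))
    stop("empty annulus: no pupil samples between NA_min and NA_max ",
         "(grid too coarse or bounds inverted)", call. = FALSE)
  vals[sel] <- 1
  pupil_field(vals, grids, spec = spec)
}

# default multi-Bessel lattice period for a symmetry (nm)
#' @keywords internal
mb_period <- function(symmetry, NA_exc, lambda_exc) {
  switch(symmetry,
    # any period below the diffraction limit leaves only the m = 0 band
    axial_sw  = 0.5 * lambda_exc / NA_exc,
    square    = lambda_exc / NA_exc,
    hexagonal = (2 / sqrt(3)) * lambda_exc / NA_exc,
    stop("no multi-Bessel period for symmetry '", symmetry,
         "' (the hexrect pattern is aperiodic)", call. = FALSE))
}

#' Coherent multi-Bessel (MB) lattice pupil
#'
#' The pupil of a coherent periodic array of annulus-bound Bessel beams:
#' `2M + 1` uniform vertical bands at `kx = 2 pi m / T`, `|m| <= M`, cropped
#' by the annulus, where `M` is the largest integer strictly below
#' `NA_exc * T / lambda_exc`. At the special periods
#' `T < lambda/NA_exc` (axial standing wave), `T = lambda/NA_exc` (square)
#' and `T = (2/sqrt(3)) lambda/NA_exc` (hexagonal) the excitation maxima
#' have the symmetry of the corresponding bound 2D optical lattice. The
#' period may be overridden through `spec$T_override`.
#'
#' @inheritParams gaussian_pupil
#' @param band_cap Maximum admissible `M` (guards against absurd periods).
#' @return A [pupil_field()] whose `beamlets` tibble lists the band index
#'   `m`, the band center `na_x`, and the annulus-cropped axial extent of
#'   each band.
#' @export
mb_pupil <- function(spec, grids, band_cap = 12L) {
  stopifnot(inherits(spec, "sheet_spec"), spec$family == "mb")
  cfg <- grids$config
  T_nm <- spec$T_override %||%
    mb_period(spec$symmetry, spec$NA_exc, cfg$lambda_exc)
  # bands survive annulus cropping iff their |kx| lies within NA_max
  dkx_na <- cfg$lambda_exc / T_nm      # band spacing in NA units
  M <- floor(spec$NA_max / dkx_na + 1e-9)
  if (M > band_cap)
    stop(sprintf("period T = %.0f nm implies %d bands (M = %d > cap %d)",
                 T_nm, 2L * M + 1L, M, band_cap), call. = FALSE)
  vals <- matrix(0 + 0i, grids$N_k, grids$N_k)
  rows <- list()
  for (m in seq.int(-M, M)) {
    na_x <- m * dkx_na                 # kx = 2 pi m / T in NA units
    j <- na_index(na_x, grids)
    na_x_snap <- grids$na_axis[j]
    rho <- sqrt(na_x_snap^2 + grids$na_axis^2)
    sel <- rho >= spec$NA_min & rho <= spec$NA_max
    if (!any(sel)) next
    vals[sel, j] <- vals[sel, j] + 1
    rows[[length(rows) + 1L]] <- tibble::tibble(
      m = m, na_x = na_x_snap,
      na_z_min = min(abs(grids$na_axis[sel])),
      na_z_max = max(abs(grids$na_axis[sel])),
      crosses_equator = abs(na_x_snap) >= spec$NA_min)
  }
  if (!length(rows))
    stop("no multi-Bessel band falls inside the annulus", call. = FALSE)
  pupil_field(vals, grids, spec = spec,
              beamlets = do.call(rbind, rows))
}

#' Axially confined (AC) lattice pupil
#'
#' Binds an ideal 2D lattice in `z` by replacing each discrete pupil
#' illumination point with a Gaussian stripe parallel to the `kz` axis. All
#' stripes share the same 1/e amplitude half-width `sigma_NA` (NA units) and
#' the ideal lattice's relative amplitudes, so every stripe carries the same
#' integrated power. In the limit `sigma_NA -> 0` the ideal delta-point
#' lattice is recovered.
#'
#' If the spec carries annulus bounds they crop the stripes radially;
#' otherwise a stripe whose significant amplitude (above 1e-8 of peak)
#' leaves the propagating circle `NA = n` raises an error.
#'
#' @inheritParams gaussian_pupil
#' @return A [pupil_field()] with per-stripe `beamlets` annotation.
#' @export
ac_pupil <- function(spec, grids) {
  stopifnot(inherits(spec, "sheet_spec"), spec$family == "ac")
  wv <- lattice_wavevectors(spec$symmetry, spec$NA_exc)
  vals <- matrix(0 + 0i, grids$N_k, grids$N_k)
  for (b in seq_len(nrow(wv))) {
    prof <- exp(-((grids$na_axis - wv$na_z[b]) / spec$sigma_NA)^2)
    col <- stripe_column(grids, wv$na_x[b], prof + 0i,
                         NA_min = spec$NA_min, NA_max = spec$NA_max,
                         what = "AC lattice stripe")
    j <- na_index(wv$na_x[b], grids)
    vals[, j] <- vals[, j] + col
  }
  wv$sigma_b <- spec$sigma_NA
  wv$amplitude <- 1
  pupil_field(vals, grids, spec = spec, beamlets = wv)
}

#' Harmonic-balanced (HB) lattice design
#'
#' Designs a lattice light sheet whose swept-OTF harmonics all have equal
#' strength and equal propagation length, by choosing per-beamlet Gaussian
#' stripe widths and amplitudes:
#'
#' 1. The symmetry fixes the ideal-lattice wave vectors (the square lattice
#'    is excluded: its equatorial beamlets overweight the DC region).
#' 2. Each beamlet is modeled as a vertical 1D Gaussian stripe of 1/e
#'    half-width `(sigma_NA)_b` at its lattice point.
#' 3. Because a beamlet's propagation length is set by the radial NA range
#'    it covers, and that range scales with the beamlet's axial direction
#'    cosine `c_b = |kz_b| / (k NA_exc)`, equal lengths require
#'    `sigma_b = sigma_ref / c_b` with the polar beamlet (`c_ref = 1`) as
#'    reference.
#' 4. `sigma_ref` is initialized from the small-width expansion of the
#'    beamlet-length formula: `sigma_ref ~ (n^2 - NA_exc^2) /
#'    (4 NA_exc) * lambda_exc / y_FWHM`.
#' 5. Equal focal-plane beam amplitudes (hence equal swept harmonics)
#'    require pupil amplitudes `(E_o)_b = c_b * (E_o)_ref`.
#' 6. Since steps 3-5 are first-order estimates, `sigma_ref` is then tuned
#'    by deterministic bisection on the simulated sheet length until the
#'    measured `y_FWHM` of `I(y, z = 0)` matches the target.
#'
#' Beamlets whose width reaches across the equatorial line `NA_z = 0`
#' (possible for the `+/-NA_exc/4` beamlets of the hexrect pattern at large
#' widths) merge into longer bands; this is reported as a warning, or as an
#' error with `on_overlap = "error"`.
#'
#' @param symmetry `"axial_sw"`, `"hexagonal"` or `"hexrect"`.
#' @param NA_exc Lattice ring NA.
#' @param y_FWHM_target Desired propagation length (nm), measured as the
#'   FWHM of the on-axis swept intensity `I(y, 0)`.
#' @param config An [optical_config()].
#' @param grids A [make_grids()] grid set.
#' @param sigma_ref Optional fixed reference width (NA units); when given
#'   and `tune = FALSE`, no calibration loop is run.
#' @param tune Run the bisection calibration of `sigma_ref` (step 6)?
#' @param NA_min,NA_max Optional annulus bounds cropping the stripes.
#' @param tol_nm Convergence tolerance on `|y_FWHM - target|`; default half
#'   a medium wavelength.
#' @param max_iter Bisection iteration cap.
#' @param on_overlap `"warn"` (default) or `"error"` when a beamlet width
#'   overlaps `NA_z = 0`.
#'
#' @return A list of class `hb_design` with elements `spec` (a
#'   [sheet_spec()] with the tuned `sigma_NA`), `pupil` (the ideal
#'   [pupil_field()]), `beamlets` (tibble with `na_x`, `na_z`, `c_b`,
#'   `sigma_b`, `amplitude`, `NA_minus`, `NA_plus`), `sigma_ref`, and the
#'   achieved `y_FWHM` (nm).
#' @export
hb_design <- function(symmetry, NA_exc, y_FWHM_target, config, grids,
                      sigma_ref = NULL, tune = TRUE,
                      NA_min = NA_real_, NA_max = NA_real_,
                      tol_nm = 0.5 * config$lambda_exc / config$n_medium,
                      max_iter = 60L,
                      on_overlap = c("warn", "error")) {
  symmetry <- match.arg(symmetry, c("axial_sw", "hexagonal", "hexrect"))
  on_overlap <- match.arg(on_overlap)
  n <- config$n_medium
  sigma0 <- sigma_ref %||%
    ((n^2 - NA_exc^2) / (4 * NA_exc) * config$lambda_exc / y_FWHM_target)

  build <- function(sref) {
    wv <- lattice_wavevectors(symmetry, NA_exc)
    wv$c_b <- abs(wv$c_b)
    wv$sigma_b <- sref / wv$c_b
    wv$amplitude <- wv$c_b
    bad <- wv$sigma_b >= abs(wv$na_z)
    if (any(bad)) {
      msg <- sprintf(paste0("%d beamlet(s) have widths overlapping NA_z = 0 ",
                            "(sigma_b >= |NA_z|); they merge into longer ",
                            "bands"), sum(bad))
      if (on_overlap == "error") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
    }
    vals <- matrix(0 + 0i, grids$N_k, grids$N_k)
    for (b in seq_len(nrow(wv))) {
      prof <- wv$amplitude[b] *
        exp(-((grids$na_axis - wv$na_z[b]) / wv$sigma_b[b])^2)
      col <- stripe_column(grids, wv$na_x[b], prof + 0i,
                           NA_min = NA_min, NA_max = NA_max,
                           what = "HB beamlet stripe")
      j <- na_index(wv$na_x[b], grids)
      vals[, j] <- vals[, j] + col
    }
    # 1/e-point radial bounds of each beamlet (used for length accounting)
    rho_lo <- sqrt(wv$na_x^2 + (abs(wv$na_z) - wv$sigma_b)^2)
    rho_hi <- sqrt(wv$na_x^2 + (abs(wv$na_z) + wv$sigma_b)^2)
    wv$NA_minus <- pmax(rho_lo, if (!is.na(NA_min)) NA_min else 0)
    wv$NA_plus <- pmin(rho_hi, if (!is.na(NA_max)) NA_max else n)
    list(pupil = pupil_field(vals, grids,
                             spec = sheet_spec("hb", symmetry = symmetry,
                                               NA_exc = NA_exc,
                                               NA_min = NA_min, NA_max = NA_max,
                                               sigma_NA = sref),
                             beamlets = wv),
         beamlets = wv)
  }

  measure <- function(sref) {
    y_fwhm_pupil(build(sref)$pupil, grids,
                 y_max = 6 * y_FWHM_target)
  }

  sref <- sigma0
  if (tune) {
    # y_FWHM decreases monotonically with sigma_ref: bisect on a fixed
    # bracket around the analytic initialization
    lo <- sigma0 / 5; hi <- sigma0 * 5
    f_lo <- measure(lo); f_hi <- measure(hi)
    if (!(f_lo >= y_FWHM_target && f_hi <= y_FWHM_target))
      stop(sprintf(paste0("hb_design: target y_FWHM = %.0f nm not ",
                          "bracketed by sigma_ref in [%.4g, %.4g] ",
                          "(lengths %.0f..%.0f nm)"),
                   y_FWHM_target, lo, hi, f_hi, f_lo), call. = FALSE)
    it <- 0L
    repeat {
      it <- it + 1L
      sref <- sqrt(lo * hi)
      f <- measure(sref)
      if (abs(f - y_FWHM_target) < tol_nm) break
      if (it >= max_iter)
        stop("hb_design: sigma_ref calibration did not converge within ",
             max_iter, " iterations", call. = FALSE)
      if (f > y_FWHM_target) lo <- sref else hi <- sref
    }
  }
  out <- build(sref)
  y_ach <- y_fwhm_pupil(out$pupil, grids, y_max = 6 * y_FWHM_target)
  structure(list(spec = out$pupil$spec, pupil = out$pupil,
                 beamlets = out$beamlets, sigma_ref = sref,
                 y_FWHM = y_ach),
            class = "hb_design")
}

#' @export
print.hb_design <- function(x, ...) {
  cat(sprintf("<hb_design> %s, NA_exc = %g, sigma_ref = %.4f NA\n",
              x$spec$symmetry, x$spec$NA_exc, x$sigma_ref))
  cat(sprintf("  achieved y_FWHM = %.0f nm (%.1f lambda_exc/n)\n", x$y_FWHM,
              x$y_FWHM * x$pupil$grids$config$n_medium /
                x$pupil$grids$config$lambda_exc))
  print(x$beamlets)
  invisible(x)
}

# band extents (kz_minus, kz_plus in NA units, per band center na_x) of a
# multi-Bessel pupil, either from the exact annulus geometry or from the
# discrete grid occupancy used by mb_pupil()
#' @keywords internal
mb_band_extents <- function(spec, grids, edges = c("analytic", "grid")) {
  edges <- match.arg(edges)
  cfg <- grids$config
  T_nm <- spec$T_override %||%
    mb_period(spec$symmetry, spec$NA_exc, cfg$lambda_exc)
  dkx_na <- cfg$lambda_exc / T_nm
  M <- floor(spec$NA_max / dkx_na + 1e-9)
  rows <- list()
  for (m in seq.int(-M, M)) {
    na_x <- m * dkx_na
    if (edges == "grid")
      na_x <- round(na_x / grids$dNA) * grids$dNA
    if (abs(na_x) > spec$NA_max) next
    kz_hi <- sqrt(spec$NA_max^2 - na_x^2)
    kz_lo <- if (abs(na_x) >= spec$NA_min) 0
    else sqrt(spec$NA_min^2 - na_x^2)
    if (edges == "grid") {
      # effective continuous edges of the discrete sample run
      kz_hi <- (floor(kz_hi / grids$dNA) + 0.5) * grids$dNA
      kz_lo <- if (kz_lo == 0) 0
      else (ceiling(kz_lo / grids$dNA) - 0.5) * grids$dNA
    }
    if (kz_hi <= kz_lo) next
    crosses <- abs(na_x) >= spec$NA_min
    rows[[length(rows) + 1L]] <- tibble::tibble(
      m = m, na_x = na_x,
      kz_minus = if (crosses) -kz_hi else kz_lo,
      kz_plus = kz_hi,
      crosses_equator = crosses)
  }
  if (!length(rows))
    stop("no band falls inside the annulus", call. = FALSE)
  do.call(rbind, rows)
}

#' Cosine-sinc (CS) swept axial profile
#'
#' The swept axial excitation profile of a multi-Bessel sheet is, by the
#' field synthesis theorem, the incoherent sum of the profiles of its
#' individual pupil bands. Each annulus-cropped uniform band of axial extent
#' `[kz_minus, kz_plus]` (appearing symmetrically at `+/-kz`) contributes
#'
#' `PSF_band(z) = (kz_range)^2 * cos^2(kz_mid * z) * sinc^2(kz_range * z / 2)`
#'
#' with `kz_mid = (kz_plus + kz_minus)/2` and `kz_range = kz_plus -
#' kz_minus`; a band crossing the equator has `kz_mid = 0` and reduces to a
#' pure `sinc^2`. Sheets realized by stepping a line of illumination
#' through the band positions (rather than writing the full lattice on an
#' SLM) produce exactly this time-averaged profile.
#'
#' @param spec A [sheet_spec()] with `family = "cs"` (or `"mb"`): requires
#'   symmetry (or `T_override`) and annulus bounds.
#' @param grids A [make_grids()] grid set; the profile is evaluated on its
#'   focal axis.
#' @param edges `"analytic"` (exact annulus geometry) or `"grid"` (match
#'   the discrete band quantization of [mb_pupil()] on the same grid).
#' @return A tibble with columns `z_nm` and `intensity` (peak-normalized),
#'   with the per-band extents attached as attribute `"bands"`.
#' @export
cs_profile <- function(spec, grids, edges = c("analytic", "grid")) {
  stopifnot(inherits(spec, "sheet_spec"), spec$family %in% c("cs", "mb"))
  bands <- mb_band_extents(spec, grids, edges = match.arg(edges))
  ko <- k_o(grids$config)
  z <- grids$x_axis
  prof <- numeric(length(z))
  for (b in seq_len(nrow(bands))) {
    kz_mid <- ko * (bands$kz_plus[b] + bands$kz_minus[b]) / 2
    kz_rng <- ko * (bands$kz_plus[b] - bands$kz_minus[b])
    arg <- kz_rng * z / 2
    snc <- ifelse(arg == 0, 1, sin(arg) / arg)
    prof <- prof + kz_rng^2 * cos(kz_mid * z)^2 * snc^2
  }
  out <- tibble::tibble(z_nm = z, intensity = prof / max(prof))
  attr(out, "bands") <- bands
  out
}
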