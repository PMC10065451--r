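#' Annular mask
#'
#' The pupil-conjugate annular mask that transmits only
#' `NA_min <= NA_rho <= NA_max`, blocking undiffracted ("DC") light and
#' unwanted higher diffraction orders from the SLM.
#'
#' @param NA_min,NA_max Inner and outer NA of the transmitting ring,
#'   `0 <= NA_min < NA_max`.
#' @return An object of class `annular_mask`.
#' @export
annular_mask <- function(NA_min, NA_max) {
  if (!(NA_min >= 0 && NA_min < NA_max))
    stop("annular mask requires 0 <= NA_min < NA_max", call. = FALSE)
  structure(list(NA_min = NA_min, NA_max = NA_max), class = "annular_mask")
}

#' @export
print.annular_mask <- function(x, ...) {
  cat(sprintf("<annular_mask> NA %g / %g\n", x$NA_max, x$NA_min))
  invisible(x)
}

# normalized real part of a focal field (the quantity written to the SLM)
#' @keywords internal
e_norm <- function(E_focal) {
  E <- if (inherits(E_focal, "focal_field")) E_focal$values else E_focal
  re <- Re(E)
  m <- max(abs(re))
  if (m == 0)
    stop("focal field has an identically zero real part; nothing to encode",
         call. = FALSE)
  re / m
}

#' Grayscale SLM phase pattern
#'
#' Encodes a focal-plane electric field on a phase-only SLM in grayscale
#' mode: the real part of the field is normalized to `[-1, 1]` and mapped to
#' phase `pi * E_norm`, with samples whose normalized magnitude does not
#' exceed the cropping factor `epsilon` set to exactly zero. Cropping
#' truncates weak sidelobes far from the central excitation maximum; the
#' sharp truncation generates sinc-like side orders flanking each pupil
#' band, which help fill troughs in the overall OTF.
#'
#' @param E_focal A [focal_field()] (typically from [pupil_to_focal()] at
#'   `y = 0`) or a complex matrix.
#' @param epsilon Cropping factor in `[0, 1)`.
#' @return An object of class `slm_pattern` with fields `phase` (radians in
#'   `[-pi, pi]`), `mode = "grayscale"`, `epsilon`.
#' @export
phase_grayscale <- function(E_focal, epsilon = 0) {
  if (epsilon < 0 || epsilon >= 1)
    stop("epsilon must lie in [0, 1)", call. = FALSE)
  En <- e_norm(E_focal)
  phase <- pi * En
  phase[abs(En) <= epsilon] <- 0
  structure(list(phase = phase, mode = "grayscale", epsilon = epsilon),
            class = "slm_pattern")
}

#' Binary SLM phase pattern
#'
#' Encodes a focal field on a binary phase SLM: samples where the
#' normalized real field exceeds `epsilon` are set to phase `pi`, samples
#' below `-epsilon` to `0`, and samples within the cropping band to `0`.
#' This is the generation mode used for multi-Bessel and axially confined
#' lattices; the diffracted pupil bands acquire variable rather than
#' uniform intensity, controlled by `epsilon`.
#'
#' @inheritParams phase_grayscale
#' @return An `slm_pattern` with `phase` in `{0, pi}` and `mode = "binary"`.
#' @export
phase_binary <- function(E_focal, epsilon = 0) {
  if (epsilon < 0 || epsilon >= 1)
    stop("epsilon must lie in [0, 1)", call. = FALSE)
  En <- e_norm(E_focal)
  phase <- ifelse(En > epsilon, pi, 0)
  structure(list(phase = phase, mode = "binary", epsilon = epsilon),
            class = "slm_pattern")
}

#' @export
print.slm_pattern <- function(x, ...) {
  cat(sprintf("<slm_pattern> %s, epsilon = %g, %.1f%% nonzero pixels\n",
              x$mode, x$epsilon, 100 * mean(x$phase != 0)))
  invisible(x)
}

#' Diffract an SLM pattern and filter with the annular mask
#'
#' Models the experimental generation path after the SLM: a uniform unit
#' plane wave acquires the pattern phase (`E = exp(i * Phi)`, a unitary
#' phase screen), the diffracted field is Fourier transformed to the pupil
#' plane, and all samples outside the annulus are zeroed. Undiffracted DC
#' light is blocked whenever `NA_min > 0`.
#'
#' @param pattern An [slm_pattern][phase_grayscale()].
#' @param mask An [annular_mask()].
#' @param grids The [make_grids()] grid set the pattern is sampled on.
#' @return The realized [pupil_field()].
#' @export
apply_slm_and_mask <- function(pattern, mask, grids) {
  stopifnot(inherits(pattern, "slm_pattern"), inherits(mask, "annular_mask"),
            inherits(grids, "grid_set"))
  if (!all(dim(pattern$phase) == c(grids$N_k, grids$N_k)))
    stop("SLM pattern grid does not match the supplied grid set",
         call. = FALSE)
  if (mask$NA_min <= 0 && mean(pattern$phase == 0) > 0.25)
    warning("mask transmits DC while a large area of the pattern has zero ",
            "phase: undiffracted light will leak into the pupil",
            call. = FALSE)
  E_slm <- exp(1i * pattern$phase)
  P <- fft2c(E_slm)
  rho <- sqrt(outer(grids$na_axis^2, grids$na_axis^2, `+`))
  P[rho < mask$NA_min | rho > mask$NA_max] <- 0
  pupil_field(P, grids)
}

#' Realize a light sheet through the SLM + annulus generation path
#'
#' Convenience wrapper chaining the full experimental model: ideal pupil ->
#' focal field at `y = 0` -> SLM phase pattern (grayscale or binary, with
#' cropping factor `epsilon`) -> diffraction -> annular-mask filtering ->
#' realized pupil.
#'
#' @param pupil The ideal [pupil_field()] of the desired sheet.
#' @param grids A [make_grids()] grid set.
#' @param mode `"grayscale"` or `"binary"`.
#' @param epsilon Cropping factor; defaults to the originating spec's value.
#' @param mask An [annular_mask()]; defaults to the spec's annulus bounds.
#' @return The realized [pupil_field()], with the SLM pattern attached as
#'   attribute `"slm_pattern"`.
#' @export
slm_realize <- function(pupil, grids, mode = c("grayscale", "binary"),
                        epsilon = NULL, mask = NULL) {
  mode <- match.arg(mode)
  spec <- pupil$spec
  epsilon <- epsilon %||% (if (!is.null(spec)) spec$epsilon else 0)
  if (is.null(mask)) {
    if (is.null(spec) || is.na(spec$NA_min) || is.na(spec$NA_max))
      stop("no annular mask given and the pupil spec carries no annulus",
           call. = FALSE)
    mask <- annular_mask(spec$NA_min, spec$NA_max)
  }
  foc <- pupil_to_focal(pupil, grids, y = 0)
  pat <- switch(mode,
                grayscale = phase_grayscale(foc, epsilon),
                binary = phase_binary(foc, epsilon))
  out <- apply_slm_and_mask(pat, mask, grids)
  out$spec <- spec
  attr(out, "slm_pattern") <- pat
  out
}
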