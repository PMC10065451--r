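#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a swept sheet into a long tibble
#'
#' @param x A [swept_sheet()].
#' @param ... Unused.
#' @return A tibble with columns `y_nm`, `z_nm`, `intensity`.
#' @method tidy swept_sheet
#' @export
tidy.swept_sheet <- function(x, ...) {
  tibble::tibble(
    y_nm = rep(x$y_planes, times = length(x$z_axis)),
    z_nm = rep(x$z_axis, each = length(x$y_planes)),
    intensity = as.vector(x$intensity))
}

#' Tidy an OTF map into a long tibble
#'
#' @param x An [otf_map].
#' @param ... Unused.
#' @return A tibble with columns `na_z`, `na_x`, `modulus`.
#' @method tidy otf_map
#' @export
tidy.otf_map <- function(x, ...) {
  tibble::tibble(
    na_z = rep(x$na_axis, times = length(x$na_axis)),
    na_x = rep(x$na_axis, each = length(x$na_axis)),
    modulus = as.vector(Mod(x$values)))
}

#' Tidy a pupil field into a long tibble of nonzero samples
#'
#' @param x A [pupil_field()].
#' @param ... Unused.
#' @return A tibble with columns `na_z`, `na_x`, `amplitude`, `phase`.
#' @method tidy pupil_field
#' @export
tidy.pupil_field <- function(x, ...) {
  ax <- x$grids$na_axis
  idx <- which(Mod(x$values) > 0, arr.ind = TRUE)
  tibble::tibble(
    na_z = ax[idx[, 1]], na_x = ax[idx[, 2]],
    amplitude = Mod(x$values[idx]), phase = Arg(x$values[idx]))
}

#' Tidy a harmonic-balanced design into its beamlet table
#'
#' @param x An [hb_design()] result.
#' @param ... Unused.
#' @return The beamlet tibble (`na_x`, `na_z`, `c_b`, `sigma_b`,
#'   `amplitude`, `NA_minus`, `NA_plus`).
#' @method tidy hb_design
#' @export
tidy.hb_design <- function(x, ...) x$beamlets

#' One-row summary of a harmonic-balanced design
#'
#' @param x An [hb_design()] result.
#' @param ... Unused.
#' @return A one-row tibble: `symmetry`, `NA_exc`, `sigma_ref`, `y_FWHM`,
#'   `n_beamlets`.
#' @method glance hb_design
#' @export
glance.hb_design <- function(x, ...) {
  tibble::tibble(symmetry = x$spec$symmetry, NA_exc = x$spec$NA_exc,
                 sigma_ref = x$sigma_ref, y_FWHM = x$y_FWHM,
                 n_beamlets = nrow(x$beamlets))
}

#' One-row summary of a stripe benchmark
#'
#' @param x A [stripe_benchmark()] result.
#' @param ... Unused.
#' @return A one-row tibble: `rl_iterations`, `min_resolved_nm`,
#'   `n_resolved`, `monotone`.
#' @method glance stripe_benchmark_result
#' @export
glance.stripe_benchmark_result <- function(x, ...) {
  tibble::tibble(rl_iterations = x$rl_iterations,
                 min_resolved_nm = x$min_resolved_nm,
                 n_resolved = sum(x$pairs$resolved),
                 monotone = x$monotone)
}

#' Plot a pupil field
#'
#' @param object A [pupil_field()].
#' @param ... Unused.
#' @return A ggplot raster of the pupil amplitude.
#' @method autoplot pupil_field
#' @export
autoplot.pupil_field <- function(object, ...) {
  df <- tibble::tibble(
    na_z = rep(object$grids$na_axis, times = object$grids$N_k),
    na_x = rep(object$grids$na_axis, each = object$grids$N_k),
    amplitude = as.vector(Mod(object$values)))
  lim <- 1.1 * object$grids$config$n_medium
  df <- df[abs(df$na_z) <= lim & abs(df$na_x) <= lim, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$na_x, .data$na_z,
                                   fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "NA_x", y = "NA_z", fill = "|E|",
                  title = "Pupil field amplitude")
}

#' Plot a swept sheet intensity profile
#'
#' @param object A [swept_sheet()].
#' @param z_window Half-width of the displayed z range (nm).
#' @param ... Unused.
#' @return A ggplot raster of `I(y, z)`.
#' @method autoplot swept_sheet
#' @export
autoplot.swept_sheet <- function(object, z_window = 5000, ...) {
  df <- tidy.swept_sheet(object)
  df <- df[abs(df$z_nm) <= z_window, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$y_nm / 1e3, .data$z_nm / 1e3,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "y (um)", y = "z (um)", fill = "I",
                  title = "Swept sheet intensity I(y, z)")
}

#' Plot an OTF map on a log scale
#'
#' @param object An [otf_map].
#' @param floor Modulus floor for the log scale.
#' @param ... Unused.
#' @return A ggplot raster of `log10 |OTF|`.
#' @method autoplot otf_map
#' @export
autoplot.otf_map <- function(object, floor = 1e-4, ...) {
  df <- tidy.otf_map(object)
  df$log_mod <- log10(pmax(df$modulus, floor))
  ggplot2::ggplot(df, ggplot2::aes(.data$na_x, .data$na_z,
                                   fill = .data$log_mod)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "kx (NA units)", y = "kz (NA units)",
                  fill = "log10|OTF|",
                  title = sprintf("OTF at y = %.0f nm", object$y_offset))
}

#' Plot a Fourier shell correlation curve
#'
#' @param object An [fsc_curve][fourier_shell_correlation()].
#' @param ... Unused.
#' @return A ggplot line plot with the threshold and cutoff marked.
#' @method autoplot fsc_curve
#' @export
autoplot.fsc_curve <- function(object, ...) {
  thr <- attr(object, "threshold")
  cut <- attr(object, "cutoff_freq")
  ggplot2::ggplot(object, ggplot2::aes(.data$shell_freq,
                                       .data$correlation)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::geom_vline(xintercept = cut, linetype = 3) +
    ggplot2::labs(x = "spatial frequency (cycles/nm)", y = "FSC",
                  title = sprintf("FSC cutoff %.4g cycles/nm", cut))
}

#' Plot a stripe benchmark modulation table
#'
#' @param object A [stripe_resolution()] table.
#' @param ... Unused.
#' @return A ggplot of modulation depth versus line-pair separation.
#' @method autoplot stripe_benchmark
#' @export
autoplot.stripe_benchmark <- function(object, ...) {
  crit <- attr(object, "criterion")
  ggplot2::ggplot(object, ggplot2::aes(.data$separation_nm, .data$depth,
                                       colour = .data$resolved)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = crit, linetype = 2) +
    ggplot2::labs(x = "line-pair separation (nm)",
                  y = "modulation depth",
                  title = sprintf("Smallest resolved pair: %.0f nm",
                                  attr(object, "min_resolved_nm")))
}

#' @rdname autoplot.swept_sheet
#' @param sheet A [swept_sheet()].
#' @export
plot_swept_sheet <- function(sheet, z_window = 5000)
  autoplot.swept_sheet(sheet, z_window = z_window)

#' @rdname autoplot.otf_map
#' @param otf An [otf_map].
#' @export
plot_otf_map <- function(otf, floor = 1e-4)
  autoplot.otf_map(otf, floor = floor)

#' @rdname autoplot.pupil_field
#' @param pupil A [pupil_field()].
#' @export
plot_pupil <- function(pupil) autoplot.pupil_field(pupil)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @keywords internal
NULL
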