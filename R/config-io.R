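#' Default run configuration
#'
#' The package defaults reproduce the reference instrument: 488 nm
#' excitation, 520 nm emission, water (n = 1.33), detection NA 1.0,
#' excitation-objective NA cap 0.60, objective tilt 32.45 degrees, with the
#' standard pupil grid and benchmark settings.
#'
#' @return A nested list matching the JSON configuration layout.
#' @export
default_run_config <- function() {
  list(
    optical = list(lambda_exc_nm = 488, lambda_det_nm = 520,
                   n_medium = 1.33, NA_det = 1.0, NA_exc_obj = 0.60,
                   tilt_alpha_deg = 32.45),
    grid = list(N_k = 1001L, NA_span = 4.0, y_extent_nm = 0, n_y = 1L),
    sheet = list(preset = "mb-hex"),
    benchmark = list(
      phantom = list(n_stripes = 28L,
                     increments_px = c(1:25, 100L, 151L),
                     stripe_extent_x_px = 799L,
                     volume_shape = c(64L, 64L, 1001L),
                     camera_pixel_nm = 108),
      noise = list(scale = 400, read_sigma = 4, offset = 100)),
    seed = 1L)
}

# recursive merge: values in `user` override `defaults`
#' @keywords internal
merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]]))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Load and validate a JSON run configuration
#'
#' Reads a JSON configuration, fills every missing field from
#' [default_run_config()], validates the result (reporting the offending
#' field path), and returns the assembled objects. An empty file (or empty
#' JSON object) yields the defaults.
#'
#' @param path Path to a JSON file.
#' @return A list of class `run_config` with elements `optical` (an
#'   [optical_config()]), `grid` (grid parameters; build with
#'   [make_grids()]), `sheet` (a [sheet_spec()] or a preset name),
#'   `benchmark` (`phantom` = [stripe_phantom_spec()], `noise` =
#'   [noise_model()]), and `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nchar(trimws(txt)) == 0) list()
  else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  cfg <- merge_config(default_run_config(), user)
  # an explicit sheet spec replaces the default preset outright
  if (!is.null(user$sheet) && is.null(user$sheet$preset))
    cfg$sheet <- user$sheet
  fail <- function(field, msg)
    stop(sprintf("config field '%s': %s", field, msg), call. = FALSE)
  o <- cfg$optical
  if (o$lambda_exc_nm <= 0) fail("optical.lambda_exc_nm", "must be positive")
  if (o$lambda_det_nm <= 0) fail("optical.lambda_det_nm", "must be positive")
  if (!(o$NA_det > 0 && o$NA_det < o$n_medium))
    fail("optical.NA_det", "must satisfy 0 < NA_det < n_medium")
  if (!(o$NA_exc_obj > 0 && o$NA_exc_obj < o$n_medium))
    fail("optical.NA_exc_obj", "must satisfy 0 < NA_exc_obj < n_medium")
  if (o$tilt_alpha_deg < 0 || o$tilt_alpha_deg >= 90)
    fail("optical.tilt_alpha_deg", "must lie in [0, 90)")
  if (cfg$grid$N_k %% 2L == 0L) fail("grid.N_k", "must be odd")
  optical <- optical_config(o$lambda_exc_nm, o$lambda_det_nm, o$n_medium,
                            o$NA_det, o$NA_exc_obj, o$tilt_alpha_deg)
  sheet <- cfg$sheet
  if (is.null(sheet$preset)) {
    args <- sheet[names(sheet) %in% names(formals(sheet_spec))]
    sheet <- tryCatch(do.call(sheet_spec, args),
                      error = function(e) fail("sheet", conditionMessage(e)))
  } else {
    if (!sheet$preset %in% llsheet_presets()$name)
      fail("sheet.preset", paste0("unknown preset '", sheet$preset, "'"))
    sheet <- sheet$preset
  }
  ph <- cfg$benchmark$phantom
  phantom <- tryCatch(
    stripe_phantom_spec(ph$n_stripes, ph$increments_px,
                        ph$stripe_extent_x_px,
                        sim_pixel_nm = 0.10 * o$lambda_exc_nm / o$n_medium,
                        volume_shape = ph$volume_shape,
                        camera_pixel_nm = ph$camera_pixel_nm),
    error = function(e) fail("benchmark.phantom", conditionMessage(e)))
  nz <- cfg$benchmark$noise
  noise <- noise_model(nz$scale, nz$read_sigma, nz$offset,
                       seed = cfg$seed %||% 1L)
  structure(list(optical = optical, grid = cfg$grid, sheet = sheet,
                 benchmark = list(phantom = phantom, noise = noise),
                 seed = as.integer(cfg$seed %||% 1L)),
            class = "run_config")
}

#' The nine reference light sheets
#'
#' Named parameter sets for the nine light sheets of the benchmark
#' comparison, all designed to a propagation length of about 50 medium
#' excitation wavelengths (except where a published parameter set fixes the
#' length): Gaussian and sinc sheets, multi-Bessel square and hexagonal
#' lattices, axially confined standing-wave / square / hexagonal lattices,
#' and harmonic-balanced hexagonal and hexagonal-rectangular lattices.
#' Parameters printed with the published sets are used verbatim; the
#' remaining free parameters (Gaussian waist, sinc bandwidth, annulus
#' width, stripe widths) are solved numerically so the simulated sheet
#' length matches the target, and are marked `solved`.
#'
#' @return A tibble with one row per preset.
#' @export
llsheet_presets <- function() {
  tibble::tibble(
    name = c("gaussian", "sinc", "mb-square", "mb-hex", "ac-sw",
             "ac-square", "ac-hex", "hb-hex", "hb-hexrect"),
    family = c("gaussian", "sinc", "mb", "mb", "ac", "ac", "ac", "hb", "hb"),
    symmetry = c("none", "none", "square", "hexagonal", "axial_sw",
                 "square", "hexagonal", "hexagonal", "hexrect"),
    NA_exc = c(NA, NA, 0.30, 0.43, 0.40, 0.30, 0.43, 0.50, 0.50),
    NA_min = c(0.40, 0.40, NA, 0.40, NA, NA, NA, 0.40, 0.40),
    NA_max = c(0.47, 0.47, NA, 0.47, NA, NA, NA, 0.60, 0.60),
    sigma_NA = c(NA, NA, NA, NA, NA, NA, NA, 0.075, 0.15),
    epsilon = c(0.10, 0.10, 0.080, 0.080, 0.050, 0.050, 0.050,
                0.010, 0.010),
    slm_mode = c("grayscale", "grayscale", "binary", "binary", "binary",
                 "binary", "binary", "grayscale", "grayscale"),
    solved = c("w0", "NA_sinc", "annulus width", "", "sigma_NA",
               "sigma_NA", "sigma_NA", "", ""),
    target_y_fwhm = c(50, 50, 50, NA, 50, 50, 50, NA, NA))
}

# numeric solvers for the free preset parameters ----------------------------

#' @keywords internal
solve_line_param <- function(make_pupil, lower, upper, target_nm, grids,
                             n_y = 201L, tol = 1e-4) {
  f <- function(p) {
    y <- tryCatch(
      y_fwhm_pupil(make_pupil(p), grids, y_max = 4 * target_nm, n_y = n_y),
      # sheet longer than the scan window: report it as far above target
      error = function(e) 100 * target_nm)
    y - target_nm
  }
  stats::uniroot(f, c(lower, upper), tol = tol)$root
}

#' Build a preset light sheet
#'
#' Constructs the ideal pupil for one of the [llsheet_presets()] (solving
#' any free parameter against the target propagation length) and, when
#' `realized = TRUE`, pushes it through the SLM + annular-mask generation
#' path with the preset's mode and cropping factor.
#'
#' @param name Preset name (see [llsheet_presets()]).
#' @param config An [optical_config()].
#' @param grids A [make_grids()] grid set.
#' @param realized Return the SLM-realized pupil instead of the ideal one?
#' @return A list with `spec` (the completed [sheet_spec()]), `pupil` (the
#'   ideal [pupil_field()]), and `realized` (the realized pupil, or `NULL`).
#' @export
preset_pupil <- function(name, config, grids, realized = FALSE) {
  tab <- llsheet_presets()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L)
    stop("unknown preset '", name, "'; see llsheet_presets()", call. = FALSE)
  lam_n <- config$lambda_exc / config$n_medium
  target <- if (!is.na(row$target_y_fwhm)) row$target_y_fwhm * lam_n else NA
  spec <- NULL; pupil <- NULL
  if (name == "gaussian") {
    # solve on the same two-line standing-wave realization that is returned
    w0 <- solve_line_param(function(w)
      gaussian_pupil(sheet_spec("gaussian", w0 = w, x_offset_NA = 0.43),
                     grids),
      300, 2000, target, grids)
    spec <- sheet_spec("gaussian", w0 = w0, NA_min = row$NA_min,
                       NA_max = row$NA_max, epsilon = row$epsilon,
                       x_offset_NA = 0.43)
    pupil <- gaussian_pupil(spec, grids)
  } else if (name == "sinc") {
    nas <- solve_line_param(function(p)
      sinc_pupil(sheet_spec("sinc", NA_sinc = p, x_offset_NA = 0.43),
                 grids),
      0.08, 0.45, target, grids)
    spec <- sheet_spec("sinc", NA_sinc = nas, NA_min = row$NA_min,
                       NA_max = row$NA_max, epsilon = row$epsilon,
                       x_offset_NA = 0.43)
    pupil <- sinc_pupil(spec, grids)
  } else if (row$family == "mb") {
    if (name == "mb-square") {
      half <- solve_line_param(function(h)
        mb_pupil(sheet_spec("mb", symmetry = "square", NA_exc = row$NA_exc,
                            NA_min = row$NA_exc - h,
                            NA_max = row$NA_exc + h), grids),
        0.005, 0.12, target, grids)
      spec <- sheet_spec("mb", symmetry = "square", NA_exc = row$NA_exc,
                         NA_min = row$NA_exc - half,
                         NA_max = row$NA_exc + half, epsilon = row$epsilon)
    } else {
      spec <- sheet_spec("mb", symmetry = row$symmetry, NA_exc = row$NA_exc,
                         NA_min = row$NA_min, NA_max = row$NA_max,
                         epsilon = row$epsilon)
    }
    pupil <- mb_pupil(spec, grids)
  } else if (row$family == "ac") {
    sg <- solve_line_param(function(s)
      ac_pupil(sheet_spec("ac", symmetry = row$symmetry,
                          NA_exc = row$NA_exc, sigma_NA = s), grids),
      0.005, 0.12, target, grids)
    spec <- sheet_spec("ac", symmetry = row$symmetry, NA_exc = row$NA_exc,
                       sigma_NA = sg, epsilon = row$epsilon)
    pupil <- ac_pupil(spec, grids)
  } else {                                   # hb families
    des <- suppressWarnings(
      hb_design(row$symmetry, row$NA_exc, 50 * lam_n, config, grids,
                sigma_ref = row$sigma_NA, tune = FALSE,
                NA_min = row$NA_min, NA_max = row$NA_max))
    spec <- des$spec
    spec$epsilon <- row$epsilon
    pupil <- des$pupil
  }
  realized_pupil <- NULL
  if (realized) {
    mask <- if (!is.na(spec$NA_min) && !is.na(spec$NA_max))
      annular_mask(spec$NA_min, spec$NA_max)
    else annular_mask(max(0.02, spec$NA_exc - 3 * (spec$sigma_NA %||% 0.05)),
                      min(config$NA_exc_obj,
                          spec$NA_exc + 3 * (spec$sigma_NA %||% 0.05)))
    realized_pupil <- slm_realize(pupil, grids, mode = row$slm_mode,
                                  epsilon = row$epsilon, mask = mask)
  }
  list(spec = spec, pupil = pupil, realized = realized_pupil)
}

# ---------------------------------------------------------------------------

# write a numeric matrix (or list of planes) as 32-bit TIFF in [0,1] with a
# JSON sidecar recording the affine scale back to physical values
#' @keywords internal
write_scaled_tiff <- function(planes, path, sidecar_extra = list()) {
  if (is.matrix(planes)) planes <- list(planes)
  lo <- min(vapply(planes, min, numeric(1)))
  hi <- max(vapply(planes, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  scaled <- lapply(planes, function(p) (p - lo) / scale)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  sidecar <- c(list(offset = lo, scale = scale, n_planes = length(planes)),
               sidecar_extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write artifacts to disk with a manifest
#'
#' Writes a named list of artifacts into `dir`, choosing the format by
#' type: complex fields (pupil/focal/OTF) as paired real/imaginary 32-bit
#' TIFF planes with a JSON sidecar carrying grid metadata and the scaling;
#' real matrices and 3D arrays as 32-bit TIFF stacks; data frames as CSV;
#' SLM patterns additionally as 8-bit PNG (phase mapped from `[-pi, pi]`);
#' everything else as JSON. A `manifest.json` listing every file with its
#' MD5 hash (plus an optional config snapshot and seed) is written last.
#'
#' @param artifacts Named list.
#' @param dir Output directory (created if needed).
#' @param config Optional configuration snapshot stored in the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(artifacts, dir, config = NULL, seed = NULL) {
  if (is.null(names(artifacts)) || any(names(artifacts) == ""))
    stop("artifacts must be a fully named list", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(f) files <<- c(files, f)
  for (nm in names(artifacts)) {
    a <- artifacts[[nm]]
    base <- file.path(dir, nm)
    if (inherits(a, "pupil_field") || inherits(a, "focal_field") ||
        inherits(a, "otf_map")) {
      v <- a$values
      p <- paste0(base, ".tif")
      write_scaled_tiff(list(Re(v), Im(v)), p,
                        sidecar_extra = list(kind = class(a)[1],
                                             pages = c("real", "imag")))
      emit(p); emit(paste0(p, ".json"))
    } else if (inherits(a, "slm_pattern")) {
      p <- paste0(base, ".tif")
      write_scaled_tiff(a$phase, p,
                        sidecar_extra = list(kind = "slm_pattern",
                                             mode = a$mode,
                                             epsilon = a$epsilon))
      emit(p); emit(paste0(p, ".json"))
      if (requireNamespace("png", quietly = TRUE)) {
        g <- paste0(base, ".png")
        png::writePNG((a$phase + pi) / (2 * pi), g)
        emit(g)
      }
    } else if (inherits(a, "swept_sheet")) {
      p <- paste0(base, ".tif")
      write_scaled_tiff(a$intensity, p,
                        sidecar_extra = list(kind = "swept_sheet",
                                             y_planes_nm = a$y_planes))
      emit(p); emit(paste0(p, ".json"))
    } else if (is.data.frame(a)) {
      p <- paste0(base, ".csv")
      utils::write.csv(a, p, row.names = FALSE)
      emit(p)
    } else if (is.array(a) && length(dim(a)) == 3L) {
      p <- paste0(base, ".tif")
      planes <- lapply(seq_len(dim(a)[3]), function(i) a[, , i])
      write_scaled_tiff(planes, p,
                        sidecar_extra = list(kind = "volume", dim = dim(a)))
      emit(p); emit(paste0(p, ".json"))
    } else if (is.matrix(a)) {
      p <- paste0(base, ".tif")
      write_scaled_tiff(a, p, sidecar_extra = list(kind = "matrix"))
      emit(p); emit(paste0(p, ".json"))
    } else {
      p <- paste0(base, ".json")
      jsonlite::write_json(a, p, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
      emit(p)
    }
  }
  manifest <- list(files = data.frame(file = basename(files),
                                      md5 = unname(tools::md5sum(files)),
                                      stringsAsFactors = FALSE),
                   seed = seed, config = config,
                   package = "llsheet")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  invisible(manifest)
}
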