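test_that("lattice wave vectors lie on the NA_exc ring with the stated counts", {
  for (sym in c("axial_sw", "square", "hexagonal", "hexrect")) {
    wv <- lattice_wavevectors(sym, 0.50)
    expect_equal(sqrt(wv$na_x^2 + wv$na_z^2), rep(0.50, nrow(wv)),
                 tolerance = 1e-12)
    expect_equal(wv$s_b^2 + wv$c_b^2, rep(1, nrow(wv)), tolerance = 1e-12)
  }
  expect_identical(nrow(lattice_wavevectors("axial_sw", 0.5)), 2L)
  expect_identical(nrow(lattice_wavevectors("square", 0.5)), 4L)
  expect_identical(nrow(lattice_wavevectors("hexagonal", 0.5)), 6L)
  expect_identical(nrow(lattice_wavevectors("hexrect", 0.5)), 14L)
  expect_error(lattice_wavevectors("heptagonal", 0.5))
})

test_that("swept axial harmonic sets follow from pairwise kz differences", {
  # enumerate kz differences of wave vectors sharing kx: these are the
  # harmonics surviving the x-average (sweep)
  harmonics <- function(sym, na) {
    wv <- lattice_wavevectors(sym, na)
    h <- c()
    for (i in seq_len(nrow(wv)))
      for (j in seq_len(nrow(wv)))
        if (abs(wv$na_x[i] - wv$na_x[j]) < 1e-12)
          h <- c(h, wv$na_z[i] - wv$na_z[j])
    sort(unique(round(h / na, 9)))
  }
  expect_equal(harmonics("hexagonal", 0.43), c(-2, -1, 0, 1, 2))
  expect_equal(harmonics("hexrect", 0.43),
               c(-2, -1.5, -1, -0.5, 0, 0.5, 1, 1.5, 2))
  expect_equal(harmonics("axial_sw", 0.43), c(-2, 0, 2))
})

test_that("gaussian pupil gives the analytic swept profile and SW equivalence", {
  cfg <- test_config()
  g <- grids_med(cfg)
  w0 <- 700
  sp1 <- sheet_spec("gaussian", w0 = w0)                      # single line
  sp2 <- sheet_spec("gaussian", w0 = w0, x_offset_NA = 0.43)  # standing wave
  sh1 <- swept_sheet(gaussian_pupil(sp1, g), g, y_planes = 0)
  sh2 <- swept_sheet(gaussian_pupil(sp2, g), g, y_planes = 0)
  # oracle: 1D transform of exp(-(kz w0)^2/4) is exp(-(z/w0)^2) (amplitude),
  # so the swept intensity is exp(-2 z^2 / w0^2)
  oracle <- exp(-2 * g$x_axis^2 / w0^2)
  expect_equal(pk_norm(sh1$intensity[1, ]), oracle, tolerance = 1e-6)
  # the two-line standing-wave realization has the same swept profile
  expect_equal(pk_norm(sh2$intensity[1, ]), pk_norm(sh1$intensity[1, ]),
               tolerance = 1e-10)
})

test_that("gaussian line clipped by the annulus warns", {
  g <- grids_small()
  sp <- sheet_spec("gaussian", w0 = 700, NA_min = 0.40, NA_max = 0.47,
                   x_offset_NA = 0.30)
  expect_warning(gaussian_pupil(sp, g), "clip")
})

test_that("sinc pupil: tri axial OTF at focus and first intensity zero", {
  cfg <- test_config()
  g <- grids_med(cfg)
  nas <- 0.25
  sh <- swept_sheet(sinc_pupil(sheet_spec("sinc", NA_sinc = nas), g), g,
                    y_planes = 0)
  # numeric swept axial OTF vs analytic triangle tri(kz / (2 ko NA_sinc));
  # the discrete line's edge sits half a sample beyond the last kept one
  nas_eff <- (floor(nas / g$dNA) + 0.5) * g$dNA
  tri <- pmax(1 - abs(g$na_axis) / (2 * nas_eff), 0)
  expect_lt(max(abs(Mod(sh$axial_otf[1, ]) - tri)), 1e-3)
  # OTF value checks: 1 at DC, 0.5 at kz = ko NA_sinc
  ctr <- ctr_of(g$N_k)
  j <- which.min(abs(g$na_axis - nas))
  expect_equal(Mod(sh$axial_otf[1, ctr]), 1, tolerance = 1e-12)
  expect_equal(Mod(sh$axial_otf[1, j]), 0.5, tolerance = 0.02)
  # first zero of the sinc^2 profile at ko NA_sinc z = pi
  z0 <- pi / (2 * pi / cfg$lambda_exc * nas)
  jz <- which.min(abs(g$x_axis - z0))
  prof <- pk_norm(sh$intensity[1, ])
  expect_lt(prof[jz], 2e-3)
  expect_error(sinc_pupil(sheet_spec("sinc", NA_sinc = 0.7), g), "objective")
})

test_that("bessel annulus is constant on the ring and empty annuli error", {
  g <- grids_small()
  pup <- bessel_pupil(sheet_spec("bessel", NA_min = 0.40, NA_max = 0.47), g)
  vals <- Mod(pup$values[Mod(pup$values) > 0])
  expect_true(all(vals == vals[1]))
  expect_error(bessel_pupil(sheet_spec("bessel", NA_min = 0.441,
                                       NA_max = 0.4415), g), "empty")
  # swept axial OTF of the annulus is nonzero throughout |kz| < 2 ko NA_max
  # with a secondary maximum near the support
  gm <- grids_med()
  sh <- swept_sheet(bessel_pupil(sheet_spec("bessel", NA_min = 0.40,
                                            NA_max = 0.47), gm), gm,
                    y_planes = 0)
  ao <- Mod(sh$axial_otf[1, ])
  inside <- abs(gm$na_axis) < 2 * 0.47 - 2 * gm$dNA
  expect_true(all(ao[inside] > 1e-6))
  # secondary maximum: local max beyond |kz| > 1.5 NA_max
  far <- which(gm$na_axis > 1.5 * 0.47 & gm$na_axis < 2 * 0.47)
  expect_gt(max(ao[far]), ao[far[1]])
})

test_that("multi-Bessel band structure follows the lattice periods", {
  cfg <- test_config()
  g <- grids_med(cfg)
  # hexagonal, NA 0.43: T = (2/sqrt(3)) lambda / NA -> 3 bands at
  # kx = 0, +/- (sqrt(3)/2) NA
  sp <- sheet_spec("mb", symmetry = "hexagonal", NA_exc = 0.43,
                   NA_min = 0.40, NA_max = 0.47)
  pup <- mb_pupil(sp, g)
  expect_equal(sort(pup$beamlets$m), c(-1L, 0L, 1L))
  expect_equal(pup$beamlets$na_x[pup$beamlets$m == 1],
               sqrt(3) / 2 * 0.43, tolerance = g$dNA)
  # square, NA 0.43: polar stripes of m = 0 plus equatorial stripes of
  # m = +/-1 at kx = +/- NA
  spq <- sheet_spec("mb", symmetry = "square", NA_exc = 0.43,
                    NA_min = 0.40, NA_max = 0.47)
  pq <- mb_pupil(spq, g)
  expect_equal(sort(pq$beamlets$m), c(-1L, 0L, 1L))
  expect_lt(abs(abs(pq$beamlets$na_x[pq$beamlets$m == 1]) - 0.43), g$dNA)
  expect_true(all(pq$beamlets$crosses_equator[abs(pq$beamlets$m) == 1]))
  # axial SW: sub-diffraction period leaves only the polar stripes of m = 0
  ssw <- sheet_spec("mb", symmetry = "axial_sw", NA_exc = 0.43,
                    NA_min = 0.40, NA_max = 0.47)
  psw <- mb_pupil(ssw, g)
  expect_identical(sort(unique(psw$beamlets$m)), 0L)
  nz <- which(Mod(psw$values) > 0, arr.ind = TRUE)
  expect_true(all(nz[, 2] == ctr_of(g$N_k)))
})

test_that("AC stripes are bound equally and recover deltas as sigma -> 0", {
  g <- grids_med()
  sp <- sheet_spec("ac", symmetry = "hexagonal", NA_exc = 0.43,
                   sigma_NA = 0.03)
  pup <- ac_pupil(sp, g)
  # equal integrated |E|^2 per column: every occupied column carries two
  # stripes (the +/-na_z partners share a kx), all bound equally
  cols <- which(colSums(Mod(pup$values)^2) > 0)
  en <- colSums(Mod(pup$values[, cols])^2)
  expect_equal(max(en) / min(en), 1, tolerance = 1e-6)
  # small-sigma limit: focal pattern period approaches the ideal lattice's
  # (sigma of order one grid sample ~ delta points)
  sp0 <- sheet_spec("ac", symmetry = "axial_sw", NA_exc = 0.43,
                    sigma_NA = 0.01)
  prof <- swept_sheet(ac_pupil(sp0, g), g, y_planes = 0)$intensity[1, ]
  # axial SW: I(z) ~ cos^2(ko NA z): period lambda/(2 NA)
  pks <- which(diff(sign(diff(prof))) == -2) + 1L
  period <- stats::median(diff(g$x_axis[pks]))
  expect_equal(period, test_config()$lambda_exc / (2 * 0.43),
               tolerance = 2 * g$dx / (test_config()$lambda_exc / 0.86))
})

test_that("AC square equatorial beamlets propagate far longer than polar", {
  cfg <- test_config()
  g <- grids_med(cfg)
  sigma <- 0.02
  wv <- lattice_wavevectors("square", 0.30)
  # fitted 1/e bounds: polar beamlet spans [NA - s, NA + s]; equatorial
  # crosses the equator, so NA_minus = NA and NA_plus = sqrt(NA^2 + s^2)
  len_polar <- beamlet_length(0.30 - sigma, 0.30 + sigma, cfg)
  len_eq <- beamlet_length(0.30, sqrt(0.30^2 + sigma^2), cfg)
  expect_gt(len_eq / len_polar, 8)
})

test_that("cosine-sinc profile equals the swept multi-Bessel profile", {
  cfg <- test_config()
  g <- grids_med(cfg)
  sp <- sheet_spec("mb", symmetry = "hexagonal", NA_exc = 0.43,
                   NA_min = 0.40, NA_max = 0.47)
  swept <- swept_sheet(mb_pupil(sp, g), g, y_planes = 0)
  cs <- cs_profile(sp, g, edges = "grid")
  a <- pk_norm(swept$intensity[1, ])
  b <- pk_norm(cs$intensity)
  # agreement over the central +/-10 um (sheet core and sidelobes); the
  # residual is rect-edge discretization, second order in the grid step
  s <- abs(g$x_axis) <= 1e4
  expect_lt(sqrt(sum((a[s] - b[s])^2) / sum(a[s]^2)), 2.5e-3)
  expect_lt(max(abs(a[s] - b[s])), 1.5e-3)
  # degenerate band: single centered band reduces to pure sinc^2
  # (period far below the diffraction limit leaves only m = 0)
  spc <- sheet_spec("cs", symmetry = "axial_sw", NA_exc = 0.10,
                    NA_min = 0, NA_max = 0.25, T_override = 500)
  csc <- cs_profile(spc, g, edges = "analytic")
  ko <- 2 * pi / cfg$lambda_exc
  arg <- ko * 0.25 * csc$z_nm
  oracle <- ifelse(arg == 0, 1, (sin(arg) / arg)^2)
  expect_equal(csc$intensity, oracle, tolerance = 1e-9)
})

test_that("field synthesis: swept profile is the incoherent sum over bands", {
  g <- grids_med()
  for (fam in list(
    mb_pupil(sheet_spec("mb", symmetry = "hexagonal", NA_exc = 0.43,
                        NA_min = 0.40, NA_max = 0.47), g),
    ac_pupil(sheet_spec("ac", symmetry = "hexagonal", NA_exc = 0.43,
                        sigma_NA = 0.03), g))) {
    whole <- swept_sheet(fam, g, y_planes = 0)$intensity[1, ]
    cols <- which(colSums(Mod(fam$values)) > 0)
    parts <- 0
    for (cc in cols) {
      Pb <- matrix(0 + 0i, g$N_k, g$N_k)
      Pb[, cc] <- fam$values[, cc]
      parts <- parts + swept_sheet(Pb, g, y_planes = 0)$intensity[1, ]
    }
    expect_lt(sqrt(sum((whole - parts)^2) / sum(whole^2)), 1e-6)
  }
})

test_that("hb_design balances widths, amplitudes and beamlet lengths", {
  cfg <- test_config()
  g <- grids_med(cfg)
  lam_n <- lambda_over_n(cfg)
  des <- hb_design("hexagonal", 0.50, 50 * lam_n, cfg, g,
                   NA_min = 0.40, NA_max = 0.60)
  b <- des$beamlets
  # widths sigma_b = sigma_ref / c_b, amplitudes = c_b
  side <- abs(b$c_b - 0.5) < 1e-9
  expect_equal(b$sigma_b[side], rep(2 * des$sigma_ref, sum(side)))
  expect_equal(b$amplitude[side], rep(0.5, sum(side)))
  expect_equal(b$sigma_b[!side], rep(des$sigma_ref, sum(!side)))
  # calibration achieved the target length
  expect_lt(abs(des$y_FWHM - 50 * lam_n), 0.5 * lam_n)
  # per-beamlet lengths (Eq-15 style on fitted bounds) agree within 20%
  lens <- beamlet_length(b$NA_minus, b$NA_plus, cfg)
  expect_lt(diff(range(lens)) / min(lens), 0.20)
  # hexrect width ratios: the NA/4 beamlets get 4x the reference width
  des2 <- suppressWarnings(
    hb_design("hexrect", 0.50, 50 * lam_n, cfg, g, sigma_ref = 0.01,
              tune = FALSE, NA_min = 0.40, NA_max = 0.60))
  b2 <- des2$beamlets
  q <- abs(abs(b2$na_z) - 0.125) < 1e-9
  expect_equal(b2$sigma_b[q], rep(0.04, sum(q)))
  # square symmetry is excluded
  expect_error(hb_design("square", 0.5, 50 * lam_n, cfg, g))
})

test_that("hb swept-OTF harmonics are balanced at focus", {
  cfg <- test_config()
  g <- grids_med(cfg)
  lam_n <- lambda_over_n(cfg)
  des <- hb_design("hexagonal", 0.50, 50 * lam_n, cfg, g,
                   NA_min = 0.40, NA_max = 0.60)
  sh <- swept_sheet(des$pupil, g, y_planes = 0)
  ao <- Mod(sh$axial_otf[1, ])
  peak_near <- function(na) {
    w <- which(abs(g$na_axis - na) < 0.1)
    max(ao[w])
  }
  h1 <- peak_near(0.50)
  h2 <- peak_near(1.00)
  expect_lt(abs(h1 - h2) / max(h1, h2), 0.10)
})
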