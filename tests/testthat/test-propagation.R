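# shared fixtures: medium grid, ideal lattices, detection OTF (computed once)
prop_fix <- local({
  cfg <- optical_config()
  g <- make_grids(cfg, NA_span = 4.0, N_k = 525L)
  det <- detection_otf(cfg, g, n_det = 301L)
  list(cfg = cfg, g = g, det = det)
})

# ideal delta-point lattice pupil on the grid
ideal_lattice_pupil <- function(symmetry, NA_exc, g) {
  wv <- lattice_wavevectors(symmetry, NA_exc)
  P <- matrix(0 + 0i, g$N_k, g$N_k)
  half <- (g$N_k - 1L) %/% 2L
  for (b in seq_len(nrow(wv))) {
    i <- as.integer(round(wv$na_z[b] / g$dNA)) + half + 1L
    j <- as.integer(round(wv$na_x[b] / g$dNA)) + half + 1L
    P[i, j] <- P[i, j] + 1
  }
  P
}

test_that("excitation PSF is nonnegative and lattice PSFs are x-periodic", {
  g <- prop_fix$g
  P <- ideal_lattice_pupil("hexagonal", 0.43, g)
  psf <- excitation_psf(P, g, 0)
  expect_true(all(psf$values >= 0))
  # x period of the lattice: T = (2/sqrt(3)) lambda / NA_exc, snapped to the
  # grid's kx quantization
  kx_na <- round(sqrt(3) / 2 * 0.43 / g$dNA) * g$dNA
  T_snap <- prop_fix$cfg$lambda_exc / kx_na
  ctr <- ctr_of(g$N_k)
  row <- psf$values[ctr, ]
  shift <- round(T_snap / g$dx)
  n <- length(row)
  expect_gt(stats::cor(row[1:(n - shift)], row[(shift + 1):n]), 0.95)
})

test_that("ideal square lattice propagates without change in y", {
  g <- prop_fix$g
  P <- ideal_lattice_pupil("square", 0.30, g)
  I0 <- excitation_psf(P, g, 0)$values
  I1 <- excitation_psf(P, g, 15000)$values
  expect_equal(I1, I0, tolerance = 1e-9)
})

test_that("excitation OTF at focus equals the pupil autocorrelation", {
  g <- prop_fix$g
  P <- ideal_lattice_pupil("axial_sw", 0.43, g)
  otf <- excitation_otf(P, g, 0)
  # oracle: discrete autocorrelation of the two delta points gives peaks at
  # 0 and +/- 2 ko NA, the outer ones half as strong as the DC peak
  ao <- Mod(otf$values[, ctr_of(g$N_k)])
  ctr <- ctr_of(g$N_k)
  # the delta points snap to the grid; the harmonic sits at exactly twice
  # the snapped offset
  off <- as.integer(round(0.43 / g$dNA))
  i2 <- ctr + 2L * off
  expect_equal(ao[ctr], 1, tolerance = 1e-9)
  expect_equal(ao[i2], 0.5, tolerance = 1e-6)
  # away from the three peaks the OTF vanishes
  keep <- seq_along(ao) != ctr & seq_along(ao) != i2 &
    seq_along(ao) != ctr - 2L * off
  expect_lt(max(ao[keep]), 1e-9)
})

test_that("hexagonal ideal lattice OTF has 19 discrete peaks", {
  g <- prop_fix$g
  P <- ideal_lattice_pupil("hexagonal", 0.43, g)
  otf <- excitation_otf(P, g, 0)
  m <- Mod(otf$values)
  peaks <- which(m > 1e-6 * max(m), arr.ind = TRUE)
  # cluster contiguous samples into peaks (quantized delta positions)
  key <- paste(peaks[, 1], peaks[, 2])
  expect_identical(nrow(peaks), 19L)
  # oracle: number of distinct pairwise difference vectors of the 6 wave
  # vectors
  wv <- lattice_wavevectors("hexagonal", 0.43)
  d <- unique(round(cbind(outer(wv$na_z, wv$na_z, `-`)[TRUE],
                          outer(wv$na_x, wv$na_x, `-`)[TRUE]), 9))
  expect_identical(nrow(d), 19L)
})

test_that("swept sheet: x-average equals the kx = 0 OTF line transform", {
  g <- prop_fix$g
  pup <- mb_pupil(sheet_spec("mb", symmetry = "hexagonal", NA_exc = 0.43,
                             NA_min = 0.40, NA_max = 0.47), g)
  sh <- swept_sheet(pup, g, y_planes = 0)
  # Fourier identity: FT_z of the x-averaged PSF = kx = 0 line of the 2D
  # excitation OTF
  otf2 <- excitation_otf(pup, g, 0)
  line <- otf2$values[, ctr_of(g$N_k)]
  line <- line / line[ctr_of(g$N_k)]
  expect_equal(Mod(sh$axial_otf[1, ]), Mod(line), tolerance = 1e-9)
  # axial OTF is DC-normalized per plane and intensity nonnegative
  expect_true(all(sh$intensity >= 0))
  expect_equal(Mod(sh$axial_otf[1, ctr_of(g$N_k)]), 1)
})

test_that("sheet energy is conserved along y and the width doubles at y_HWHM", {
  cfg <- prop_fix$cfg
  g <- prop_fix$g
  pup <- gaussian_pupil(sheet_spec("gaussian", w0 = 700), g)
  lam_n <- lambda_over_n(cfg)
  sh <- swept_sheet(pup, g, y_planes = seq(0, 30 * lam_n, length.out = 16))
  en <- rowSums(sh$intensity)
  expect_lt(diff(range(en)) / mean(en), 1e-6)
  # y where I(y,0) drops to half
  ctr <- ctr_of(g$N_k)
  on_axis <- sh$intensity[, ctr]
  i_h <- which(on_axis <= on_axis[1] / 2)[1]
  half_width <- function(I) {
    ipk <- which.max(I)
    j <- ipk + which(I[(ipk + 1):length(I)] < I[ipk] / 2)[1]
    frac <- (I[j - 1] - I[ipk] / 2) / (I[j - 1] - I[j])
    2 * (j - 1 + frac - ipk)
  }
  w0 <- half_width(sh$intensity[1, ])
  wh <- half_width(sh$intensity[i_h, ])
  expect_gt(wh / w0, 1.5)
  expect_lt(wh / w0, 3.0)
})

test_that("detection OTF has the right supports and missing cone", {
  cfg <- prop_fix$cfg
  det <- prop_fix$det
  g <- prop_fix$g
  ctr <- ctr_of(g$N_k)
  expect_equal(det$slice_values[ctr, ctr], 1, tolerance = 1e-9)
  # missing cone: OTF(0, kz) vanishes off DC
  axial_cut <- abs(det$slice_values[, ctr])
  off <- abs(g$na_axis) > 0.05 & abs(g$na_axis) < 0.3
  expect_lt(max(axial_cut[off]), 0.01)
  # lateral support radius 2 NA_det / lambda_det (in NA units of the grid:
  # 2 NA_det lambda_exc / lambda_det)
  lat_cut <- abs(det$slice_values[ctr, ])
  lat_na <- 2 * cfg$NA_det * cfg$lambda_exc / cfg$lambda_det
  inside <- abs(g$na_axis) < 0.92 * lat_na
  outside <- abs(g$na_axis) > 1.05 * lat_na
  expect_gt(min(lat_cut[inside]), 1e-5)
  expect_lt(max(lat_cut[outside]), 1e-3)
  # bowtie maximum axial half-width matches the closed form
  mask <- abs(det$slice_values) > 1e-3
  kz_max_na <- max(abs(g$na_axis[apply(mask, 1, any)]))
  bowtie_na <- (cfg$n_medium - sqrt(cfg$n_medium^2 - cfg$NA_det^2)) /
    cfg$lambda_det * cfg$lambda_exc
  expect_equal(kz_max_na, bowtie_na, tolerance = 0.04)
})

test_that("overall swept OTF places detection copies at the harmonics", {
  cfg <- prop_fix$cfg
  g <- prop_fix$g
  det <- prop_fix$det
  ctr <- ctr_of(g$N_k)
  # delta axial OTF (ideal thin sheet): overall = detection bowtie unchanged
  thin <- swept_sheet(gaussian_pupil(sheet_spec("gaussian", w0 = 1e5), g),
                      g, y_planes = 0)
  # w0 huge -> sheet nearly uniform -> axial OTF ~ delta at DC
  ov0 <- overall_swept_otf(thin, det, 0)
  expect_equal(Mod(ov0$values[ctr, ]), abs(det$slice_values[ctr, ]),
               tolerance = 1e-3)
  # axial SW: three copies at 0, +/- 2 ko NA_exc on the half-lateral line
  sw <- swept_sheet(ideal_lattice_pupil("axial_sw", 0.43, g), g,
                    y_planes = 0)
  ov <- overall_swept_otf(sw, det, 0)
  j <- which.min(abs(g$na_axis - cfg$NA_det * cfg$lambda_exc /
                       cfg$lambda_det))
  cut <- Mod(ov$values[, j])
  pk <- which(diff(sign(diff(cut))) == -2) + 1L
  pk <- pk[cut[pk] > 0.05 * max(cut)]
  got <- sort(g$na_axis[pk])
  expect_equal(got, c(-2 * 0.43, 0, 2 * 0.43), tolerance = 0.03)
  # hexagonal: five copies at 0, +/-1, +/-2 ko NA_exc. On the half-lateral
  # line neighboring copies overlap, so check the harmonic positions on the
  # kx = 0 line, where the detection OTF contributes only at DC and the
  # excitation harmonics appear unblurred.
  hx <- swept_sheet(ideal_lattice_pupil("hexagonal", 0.43, g), g,
                    y_planes = 0)
  ovh <- overall_swept_otf(hx, det, 0)
  cuth <- Mod(ovh$values[, ctr])
  off43 <- as.integer(round(0.43 / g$dNA))
  harm <- ctr + c(-2L, -1L, 0L, 1L, 2L) * off43
  pkh <- which(diff(sign(diff(cuth))) == -2) + 1L
  pkh <- pkh[cuth[pkh] > 1e-3]
  # every detected peak is a harmonic and every harmonic is detected,
  # to within one kz grid sample
  expect_true(all(vapply(pkh, function(p) min(abs(p - harm)) <= 1L,
                         logical(1))))
  expect_true(all(vapply(harm, function(h) min(abs(pkh - h)) <= 1L,
                         logical(1))))
  # Hermitian, |OTF| <= 1, DC = 1
  v <- ovh$values
  expect_equal(v, Conj(v[nrow(v):1, ncol(v):1]), tolerance = 1e-8)
  expect_lt(max(Mod(v)), 1 + 1e-9)
  expect_equal(Mod(v[ctr, ctr]), 1)
})

test_that("MB harmonics persist to y_HWHM while AC top harmonics decay", {
  cfg <- prop_fix$cfg
  g <- prop_fix$g
  lam_n <- lambda_over_n(cfg)
  peak_near <- function(ao, na, w = 0.1)
    max(ao[abs(g$na_axis - na) < w])
  # MB hexagonal: amplitude ratios at y_HWHM within 25% of focal ones
  mp <- mb_pupil(sheet_spec("mb", symmetry = "hexagonal", NA_exc = 0.43,
                            NA_min = 0.40, NA_max = 0.47), g)
  y_h <- y_fwhm_pupil(mp, g, y_max = 60 * lam_n) / 2
  shm <- swept_sheet(mp, g, y_planes = c(0, y_h))
  r0 <- peak_near(Mod(shm$axial_otf[1, ]), 2 * 0.43) /
    peak_near(Mod(shm$axial_otf[1, ]), 0.43)
  rh <- peak_near(Mod(shm$axial_otf[2, ]), 2 * 0.43) /
    peak_near(Mod(shm$axial_otf[2, ]), 0.43)
  expect_lt(abs(rh - r0) / r0, 0.25)
  # AC hexagonal: the +/- 2 ko NA copy decays by >= 3x over the same range
  ap <- ac_pupil(sheet_spec("ac", symmetry = "hexagonal", NA_exc = 0.43,
                            sigma_NA = 0.03), g)
  y_ha <- y_fwhm_pupil(ap, g, y_max = 60 * lam_n) / 2
  sha <- swept_sheet(ap, g, y_planes = c(0, y_ha))
  a0 <- peak_near(Mod(sha$axial_otf[1, ]) /
                    max(Mod(sha$axial_otf[1, ])), 2 * 0.43)
  ah <- peak_near(Mod(sha$axial_otf[2, ]) /
                    max(Mod(sha$axial_otf[2, ])), 2 * 0.43)
  expect_gt(a0 / ah, 3)
})

test_that("overall PSF is a unit-sum product with the sheet profile", {
  cfg <- prop_fix$cfg
  g <- prop_fix$g
  pup <- gaussian_pupil(sheet_spec("gaussian", w0 = 700), g)
  sh <- swept_sheet(pup, g, y_planes = 0)
  det_psf <- detection_psf_volume(cfg, dims = c(21L, 21L, 61L),
                                  voxel_nm = 100)
  ov <- overall_psf(sh, det_psf, y = 0)
  expect_equal(sum(ov), 1, tolerance = 1e-12)
  # z marginal equals sheet profile times detection z marginal
  mz_det <- apply(det_psf, 3, sum)
  mz_ov <- apply(ov, 3, sum)
  z_ax <- (seq_len(61) - 31) * 100
  prof <- exp(-2 * z_ax^2 / 700^2)
  oracle <- prof * mz_det
  expect_equal(mz_ov / sum(mz_ov), oracle / sum(oracle), tolerance = 1e-3)
  # overall z width is below the detection-only z width
  fw <- function(v) sum(v >= max(v) / 2)
  expect_lt(fw(mz_ov), fw(mz_det) + 1)
})

test_that("SIM support: hexagonal extension, swept-equal axial, hexrect rejected", {
  cfg <- prop_fix$cfg
  s <- sim_support("hexagonal", 0.46, cfg, NA_exc_max = 0.56)
  expect_equal(round(s$R_x_SIM), 183)
  expect_equal(s$R_z_max,
               resolution_limits(cfg, 0.56)$R_z_max, tolerance = 1e-12)
  expect_error(sim_support("hexrect", 0.46, cfg), "SIM")
})
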