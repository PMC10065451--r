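# llsheet

Design and simulation of light-sheet microscopy illumination in R.

Light-sheet (selective-plane) microscopes image one plane of a living
specimen at a time with a thin sheet of excitation light. The sheet's
axial profile sets the axial resolution and optical sectioning; the
distance over which that profile survives propagation sets the field of
view; and the two fight each other. Structured sheets — lattice light
sheets — beat the Gaussian trade-off, but comparing families fairly
requires simulating each one's pupil field, its realization on a spatial
light modulator (SLM), its transfer functions versus propagation
distance, and finally what a deconvolved image actually resolves at a
realistic photon budget. `llsheet` implements that whole chain for
microscopists and instrument builders choosing or designing a sheet.

## What it computes

Working in the scalar approximation, with `z` the detection axis, `y`
the propagation axis and `x` the sweep axis, the pupil field
`E(kx, kz)` (NA units, `k = k_o NA`, `k_o = 2*pi/lambda_exc`) propagates
as

    E(x, z; y) = IFT{ E(kx, kz) exp(i ky y) },
    ky = sqrt((n k_o)^2 - kx^2 - kz^2),

the stationary PSF is `|E|^2`, the excitation OTF is its transform
(the pupil autocorrelation at focus), and sweeping keeps the `kx = 0`
line of the OTF. On top of this core the package provides:

* **pupil synthesis** for Gaussian, sinc, Bessel-annulus, multi-Bessel
  lattice (axial standing-wave / square / hexagonal), axially confined
  lattice, harmonic-balanced lattice and cosine-sinc sheets
  (`gaussian_pupil()`, `sinc_pupil()`, `bessel_pupil()`, `mb_pupil()`,
  `ac_pupil()`, `hb_design()`, `cs_profile()`);
* the **SLM generation path**: grayscale or binary phase encoding with a
  sidelobe cropping factor, diffraction, and annular-mask filtering
  (`phase_grayscale()`, `phase_binary()`, `apply_slm_and_mask()`,
  `slm_realize()`);
* **propagation and transfer functions**: swept sheet profiles
  `I(y, z)`, per-plane axial OTFs, a scalar-Debye detection OTF with its
  missing cone, and overall swept OTFs and PSFs (`swept_sheet()`,
  `detection_otf()`, `overall_swept_otf()`, `overall_psf()`);
* **metrics**: propagation lengths, beamlet lengths, closed-form and
  numerically measured resolution limits, the OTF gap criterion,
  structured-illumination support, cumulative axial confinement, tilted
  specimen-frame projections (`y_fwhm()`, `beamlet_length()`,
  `resolution_limits()`, `gap_criterion()`, `sim_support()`,
  `cumulative_intensity()`, `specimen_projection()`);
* the **stripe-phantom benchmark**: a variable-pitch test pattern imaged
  with a camera noise model, Richardson-Lucy deconvolution with
  Fourier-shell-correlation-guided stopping, and modulation-depth
  scoring of the smallest resolved line pair (`stripe_benchmark()` and
  its parts `make_stripe_phantom()`, `simulate_image()`,
  `richardson_lucy()`, `fourier_shell_correlation()`,
  `select_rl_iterations()`, `stripe_resolution()`);
* `llsheet_presets()` / `preset_pupil()` for the nine reference sheets
  of the comparison (all about 50 medium wavelengths long), JSON run
  configuration (`load_config()`), TIFF/CSV/JSON export with a hashed
  manifest (`write_outputs()`), and `tidy()` / `glance()` / `autoplot()`
  methods for every result type.

## Worked example

Characterize a hexagonal multi-Bessel lattice sheet (ring NA 0.43,
annulus 0.47/0.40), realize it through a binary SLM with cropping factor
0.080, and benchmark it:

```r
library(llsheet)
cfg <- optical_config()                 # 488/520 nm, water, NA_det 1.0
g <- make_grids(cfg, NA_span = 4.0, N_k = 1001L)
lam_n <- cfg$lambda_exc / cfg$n_medium  # one medium wavelength, 366.9 nm

spec <- sheet_spec("mb", symmetry = "hexagonal", NA_exc = 0.43,
                   NA_min = 0.40, NA_max = 0.47, epsilon = 0.080)
pupil <- mb_pupil(spec, g)

y_fwhm_pupil(pupil, g, y_max = 60 * lam_n) / lam_n
#> [1] 48.29931

resolution_limits(cfg, NA_exc_max = 0.47, symmetry = "hexagonal",
                  NA_exc = 0.43)
#> # A tibble: 1 x 7
#>   NA_exc_max R_x_swept R_z_axis R_z_max R_x_SIM R_x_specimen R_z_specimen
#>        <dbl>     <dbl>    <dbl>   <dbl>   <dbl>        <dbl>        <dbl>
#> 1       0.47       260     519.    357.    186.           NA           NA

realized <- slm_realize(pupil, g, mode = "binary")
sheet <- swept_sheet(realized, g, y_planes = 0)
bench <- stripe_benchmark(
  sheet, cfg, stripe_phantom_spec(volume_shape = c(24L, 24L, 1001L)),
  noise_model(seed = 1), max_iter = 60L)
glance(bench)
#> # A tibble: 1 x 4
#>   rl_iterations min_resolved_nm n_resolved monotone
#>           <int>           <dbl>      <int> <lgl>
#> 1            60            440.         17 FALSE
```

Reading the numbers: the sheet keeps its focal profile over 48.3 medium
wavelengths (17.7 um) of propagation. In the swept mode its lateral
resolution is detection-limited at 260 nm; along the detection axis the
excitation harmonics alone support 519 nm, improving to 357 nm at the
lateral offset where the detection OTF is axially widest, and a
structured-illumination readout would reach 186 nm laterally. After
FSC-guided Richardson-Lucy deconvolution of the noisy stripe phantom
(peak SNR 20), every line pair down to 440 nm separation stays resolved
at modulation depth >= 0.10 (`monotone = FALSE` flags isolated
sub-support detections, which are excluded from the headline number).

`autoplot(pupil)`, `autoplot(sheet)` and
`autoplot(overall_swept_otf(...))` draw the standard panels; the
vignette (`vignettes/lattice-light-sheets.Rmd`) documents the model, the
harmonic-balancing design algorithm, the benchmark conditions and the
package's numerical choices.

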