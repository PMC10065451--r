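---
title: "Designing and benchmarking lattice light-sheet illumination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and benchmarking lattice light-sheet illumination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(llsheet)
```

## The physical model

In light-sheet microscopy a thin plane of excitation light, confined along
the detection axis `z` and propagating along `y`, is swept along `x` to
illuminate one plane of a specimen at a time. The sheet's axial profile
sets the axial resolution and optical sectioning; the distance over which
that profile stays close to its focal form sets the usable field of view.
`llsheet` simulates this trade-off for the major light-sheet families in
the scalar approximation.

Every simulation starts from the **rear pupil** of the excitation
objective. A pupil field `E(kx, kz)` (coordinates in NA units, so the
transverse wavenumbers are `k = k_o * NA` with `k_o = 2*pi/lambda_exc`)
propagates to the specimen as an angular spectrum of plane waves,

```
E(x, z; y) = IFT2{ E(kx, kz) * exp(i * ky * y) },
ky = sqrt((n k_o)^2 - kx^2 - kz^2),
```

implemented as a unitary centered FFT pair on odd-sized conjugate grids
(`make_grids()`), so that total power is conserved exactly at every
propagation distance and the zero frequency is an exact sample. Pupil
content outside the propagating circle `NA = n` is rejected with an error
rather than silently zeroed: it always indicates a configuration mistake.

The stationary excitation PSF is `|E|^2`; its transform is the excitation
OTF, which at the focal plane equals the autocorrelation of the pupil
field. Sweeping along `x` time-averages the pattern, which keeps only the
`kx = 0` line of the excitation OTF; `swept_sheet()` computes the swept
profile `I(y, z)` and its per-plane axial OTF directly from that identity.

## The sheet families

All seven families are generated by `sheet_spec()` plus a synthesizer:

* **Gaussian** (`gaussian_pupil()`): a vertical pupil line with profile
  `exp(-(kz w0)^2/4)`, the transform of a focal amplitude
  `exp(-(z/w0)^2)`. A lateral offset `x_offset_NA` produces the two-line
  standing-wave realization that clears the annular mask; its swept
  profile is identical to the single line's.
* **sinc** (`sinc_pupil()`): a uniform line truncated at `NA_sinc`,
  giving a `sinc^2(k_o NA_sinc z)` focal profile and a triangular swept
  axial OTF. This is the sheet produced by cropping a broad illumination
  line with a slit or annulus.
* **Bessel annulus** (`bessel_pupil()`): uniform amplitude between
  `NA_min` and `NA_max`.
* **Multi-Bessel lattices** (`mb_pupil()`): `2M+1` uniform vertical bands
  of period `2*pi/T` in `kx`, cropped by the annulus. At
  `T < lambda/NA_exc`, `T = lambda/NA_exc` and
  `T = (2/sqrt(3)) lambda/NA_exc` the excitation maxima acquire axial
  standing-wave, square and hexagonal lattice symmetry respectively. The
  band inventory is implemented as "keep every band whose `|kx|` lies
  within the annulus": for the square period this correctly retains the
  equatorial bands that sit exactly on the ring.
* **Axially confined lattices** (`ac_pupil()`): each ideal-lattice pupil
  point replaced by a Gaussian stripe of common width `sigma_NA` (NA
  units, the 1/e amplitude = 1/e^2 intensity half-width), confining the
  sheet independently of the annulus.
* **Harmonic-balanced lattices** (`hb_design()`): see below.
* **Cosine-sinc sheets** (`cs_profile()`): the band-by-band incoherent
  equivalent of a multi-Bessel sheet. By the field synthesis theorem the
  swept profile of any multi-band pupil equals the incoherent sum of its
  per-band profiles; each annulus-cropped band contributes
  `kz_range^2 * cos^2(kz_mid z) * sinc^2(kz_range z / 2)`. The package
  verifies the theorem numerically (relative L2 below 1e-6 when summing
  per-column swept profiles).

```{r families, fig.height = 4}
cfg <- optical_config()      # 488/520 nm, water, NA_det 1.0
g <- make_grids(cfg, NA_span = 4.0, N_k = 525L)
mb <- mb_pupil(sheet_spec("mb", symmetry = "hexagonal", NA_exc = 0.43,
                          NA_min = 0.40, NA_max = 0.47), g)
autoplot(mb)
```

## The experimental generation path

Experimentally, a sheet is written on a phase-only SLM conjugate to the
specimen: the normalized real part of the focal field maps to phase
`pi * E_norm`, with samples below the cropping factor `epsilon` set to
zero (`phase_grayscale()`, `phase_binary()`). The diffracted field passes
an annular mask that blocks undiffracted light (`apply_slm_and_mask()`;
`slm_realize()` chains the whole path). Two modeling notes:

* The incident illumination is modeled as a uniform unit plane wave; the
  cylindrical-lens beam shaping upstream of the SLM affects absolute
  efficiency only, not the band structure that every downstream metric
  uses.
* Full `±pi` phase modulation is strongly overmodulated: a cosinusoidal
  field maps to `exp(i*pi*cos(...))`, which spreads power across odd
  diffraction orders as `J_m(pi)`. The realized pupil bands therefore sit
  exactly at the ideal band positions but with nonuniform intensity
  controlled by `epsilon`, and pointwise intensity fidelity of the
  reconstruction is limited to roughly 20% in relative L2. This is a
  property of the encoding, not a numerical artifact.

The cropping factor matters more than it may appear: in binary mode the
focal envelope is flattened completely, so `epsilon` alone decides the
sheet's effective axial extent and hence the realized pupil band widths
and the propagation length.

## Harmonic balancing

A lattice sheet's swept OTF consists of copies of the detection OTF at
the lattice's axial harmonics. For multi-Bessel sheets all beamlets span
the same radial annulus and so share one propagation length, but the
harmonic strengths are uneven; for axially confined sheets the beamlets
share strength but not length. `hb_design()` combines the two:

1. the symmetry fixes the beamlet positions (square is excluded — its
   equatorial beamlets only overweight DC);
2. each beamlet is a vertical Gaussian stripe; its propagation length is
   set by the radial NA range it covers, which scales with its axial
   direction cosine `c_b`, so equal lengths require widths
   `sigma_b = sigma_ref / c_b` (polar reference, `c_ref = 1`);
3. equal focal amplitudes (hence equal harmonics) require pupil
   amplitudes proportional to `c_b`;
4. `sigma_ref` is initialized from the small-width expansion
   `sigma_ref ~ (n^2 - NA_exc^2)/(4 NA_exc) * lambda/y_FWHM` and then
   calibrated by deterministic bisection against the simulated sheet
   length until the measured `y_FWHM` of `I(y, 0)` hits the target
   (tolerance half a medium wavelength, fixed bracket `sigma0/5` to
   `5*sigma0`). The bisection is the package's concrete reading of the
   published procedure's "adjust the reference width empirically".

```{r hb}
lam_n <- cfg$lambda_exc / cfg$n_medium
des <- hb_design("hexagonal", 0.50, 53 * lam_n, cfg, g,
                 NA_min = 0.40, NA_max = 0.60)
glance(des)
tidy(des)
```

The balanced design keeps the `±k_o NA_exc` and `±2 k_o NA_exc` swept-OTF
peaks equal within 10% at focus and preserves their ratio within 25% out
to the half-maximum edge of the propagation range; both properties are
asserted in the test suite.

One caveat a user should know: for the hexagonal-rectangular (hexrect)
pattern at large widths the `±NA_exc/4` beamlets' stripes can reach
across the equator and merge — the design warns (or errors with
`on_overlap = "error"`). And the published hexagonal example that pairs a
reference width of 0.075 NA with a 53-wavelength propagation length is
not reproducible under this beamlet model (0.075 NA gives a sheet about
2.5x shorter, both by the closed-form length formula and by simulation,
under every width convention we tried); the package therefore treats the
target length, not the width, as the design input, which is also what the
calibration step does.

## Resolution metrics

`resolution_limits()` evaluates the support-radius limits: lateral swept
resolution `lambda_det/(2 NA_det)`; axial resolution along the detection
axis `lambda_exc/(2 NA_exc_max)` (on the `kx = 0` axis the detection OTF
contributes only at DC because of its missing cone); and the best axial
resolution `1/(2 NA_exc_max/lambda_exc + (n - sqrt(n^2 -
NA_det^2))/lambda_det)`, attained where the detection "bowtie" is widest.
The effective `NA_exc_max` of a Gaussian-beamlet lattice is
`min(NA_exc + sigma_ref, annulus NA_max)`. `sim_support()` adds the
structured-illumination lateral extension (`sqrt(3) k_o NA_exc` for
hexagonal, `2 k_o NA_exc` for square; the aperiodic hexrect pattern
cannot be phase-stepped coherently and is rejected). `gap_criterion()`
gives the ring NA beyond which the detection-OTF copies of an axial
standing wave separate completely.

```{r limits}
resolution_limits(cfg, NA_exc_max = 0.56, symmetry = "hexagonal",
                  NA_exc = 0.46)
```

The detection OTF itself (`detection_otf()`) comes from a scalar Debye
model — the uniform spherical pupil cap at the emission wavelength —
computed on an internal grid sized to Nyquist-resolve the lateral
support, projected along the sweep axis and resampled onto the pupil
grid. Apodization is omitted deliberately: every metric used here
depends only on support geometry, which apodization does not move.
Specimen-frame resolutions account for the objective tilt by scanning
the numerically thresholded support along the rotated axes
(`specimen_projection()`).

## The stripe-phantom benchmark

Support radii bound what is recoverable; what is *practically* resolved
at finite photon budget is measured by the benchmark pipeline
(`stripe_benchmark()`):

1. a binary phantom of 28 single-voxel planes normal to `z`, with
   successive separations of 1..25 simulation pixels then 100 and 151,
   at a voxel of one tenth of the medium excitation wavelength (36.7 nm
   at 488 nm in water);
2. convolution with the overall swept PSF (detection PSF times the sheet
   profile), integer binning to the camera pixel (three voxels,
   110.1 nm), normalization by the 99.9th percentile, scaling by 400
   (peak SNR 20), variance-matched Gaussian shot noise `N(0, I_i)`, read
   noise `N(0, 4^2)` and a 100-count offset — all reproducible under a
   seed;
3. Richardson-Lucy deconvolution, with the iteration count either fixed
   or selected by Fourier shell correlation between two
   independent-noise reconstructions (threshold 1/7, a community
   standard the source material does not override);
4. modulation-depth scoring of every adjacent line pair; a pair is
   resolved at depth 0.10, and the headline number is the smallest
   separation from which all larger separations stay resolved (isolated
   sub-support "resolved" pairs are noise artifacts of heavily iterated
   deconvolution and are excluded but reported).

Because the phantom is laterally uniform, its axial image content is
governed by the sheet profile — the detection OTF's missing cone means
widefield detection adds no sectioning for such a target — so the
default volumes keep a reduced lateral extent (64 x 64 x 1001 simulation
voxels; the tests use 24 x 24) with no effect on the linecut physics.
The forward model still uses the full 3D PSF.

Two deliberate simplifications: shot noise is the Gaussian approximation
of Poisson noise with pixel-matched variance (as the reference protocol
specifies), and the camera pixel is the nearest integer multiple of the
simulation voxel (110.1 nm rather than 108 nm).

What the benchmark does and does not show: the phantom is noise-matched
and geometry-matched to the published simulations, but it has no
out-of-focus background from thick samples, no aberrations and no
registration error, so passing it demonstrates correctness of the
illumination/deconvolution chain, not performance on real tissue.

## Problem sizes and numerical choices

* Default pupil grid: `N_k = 1001`, `NA_span = 4.0` NA units, giving
  122 nm focal sampling over a 122 um field. The span is chosen so the
  *detection* OTF's lateral support (1.877 NA units in excitation NA) is
  Nyquist-resolved; grid span beyond `NA = n` carries no pupil content
  but provides transfer-function headroom. Doubling `N_k` moves sheet
  width metrics by under 0.5% (tested).
* Sheet lengths are measured as the FWHM of `I(y, 0)` by linear
  interpolation; `y_HWHM` is the half-maximum point of the same profile.
* Quantitative tests run at `N_k = 525`, the benchmarks at
  `N_k = 1001` with the reduced lateral phantom; the full suite fits in
  a few minutes on one core.
* Line-pupil parameters solved against a target length (the Gaussian
  waist and sinc bandwidth of the 50-wavelength reference sheets) are
  solved on the same two-line offset realization that is returned, since
  the offset changes the radial wavenumber spread and hence the length.
  The solved sinc bandwidth (0.240 NA) implies a theoretical axial limit
  of 1017 nm for that sheet, matching the published theoretical value.

## Known limitations

* Scalar diffraction only: no polarization-resolved excitation, no
  high-NA apodization of the excitation objective (uniform angular
  weighting; the source text states the scalar approximation but no
  apodization factor).
* The detection model is the scalar cap; a vectorial Richards-Wolf model
  is a documented extension point and would change OTF magnitudes but
  not supports.
* Confocal-slit and incoherent structured-illumination readout modes are
  out of scope, as are aberrations, tiling and photobleaching kinetics
  beyond the cumulative-intensity confinement curve
  (`cumulative_intensity()`).
* The FSC iteration ladder on this noise model typically grows to the
  configured cap rather than peaking; the cap (default 60) is therefore
  part of the benchmark conditions and is reported alongside the result.
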