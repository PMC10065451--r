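# shared fixtures: the reference optical frame and small/medium grids.
# Grid sizes are composite odd numbers (fast mixed-radix transforms); the
# small grid is for structural checks, the medium one for quantitative
# width measurements.

test_config <- function() optical_config()

grids_small <- function(config = test_config())
  make_grids(config, NA_span = 4.0, N_k = 315L)

grids_med <- function(config = test_config())
  make_grids(config, NA_span = 4.0, N_k = 525L)

lambda_over_n <- function(config = test_config())
  config$lambda_exc / config$n_medium

# center index of an odd-sized axis
ctr_of <- function(n) (n + 1L) %/% 2L

# peak-normalized vector
pk_norm <- function(v) v / max(v)

# forward model convolution (internal helper, re-exposed for tests)
fft_convolve_same_for_tests <- function(vol, psf)
  llsheet:::fft_convolve_same(vol, psf)
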