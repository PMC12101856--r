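# Shared fixtures: small, fast generator configurations built in code.

# Coarse-grid version of the default configuration (176 channels) for
# pipeline-level tests where full spectral resolution is irrelevant.
quick_config <- function(...) {
  generator_config(grid_step = 8, ...)
}

# One isolated Lorentzian band with known analytic form; no baseline.
single_band_config <- function(center = 800, width = 8, amplitude = 2,
                               gh_sensitivity = 0.6, te_sensitivity = 0,
                               additive_noise_sd = 0,
                               multiplicative_jitter_sd = 0) {
  generator_config(
    grid_min = 400, grid_max = 1200, grid_step = 2,
    band_table = data.frame(center = center, width = width,
                            base_amplitude = amplitude,
                            gh_sensitivity = gh_sensitivity,
                            te_sensitivity = te_sensitivity),
    additive_noise_sd = additive_noise_sd,
    multiplicative_jitter_sd = multiplicative_jitter_sd,
    baseline_coefficients = 0)
}

# Noise-free copy of an arbitrary configuration.
noise_free <- function(config = generator_config()) {
  config$additive_noise_sd <- 0
  config$multiplicative_jitter_sd <- 0
  config
}

# Build a spectrum_set directly from an intensity matrix.
make_set <- function(intensities, wavenumbers = NULL, ...) {
  if (is.null(dim(intensities))) intensities <- rbind(intensities)
  if (is.null(wavenumbers)) {
    wavenumbers <- seq(400, by = 2, length.out = ncol(intensities))
  }
  md <- data.frame(spectrum_id = paste0("s", seq_len(nrow(intensities))),
                   ...)
  spectrum_set(wavenumbers, intensities, md)
}
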