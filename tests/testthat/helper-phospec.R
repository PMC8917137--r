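# Shared fixtures and small numerical utilities for the suite.

# trapezoid quadrature, used as the independent numerical-area oracle
trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

gauss_area <- function(amplitude, sigma) amplitude * sigma * sqrt(2 * pi)

# small random spectrum set for i/o round trips
random_set <- function(n_samples = 3, n_points = 40, seed = 42) {
  withr::with_seed(seed, {
    w <- seq(600, 600 + 2 * (n_points - 1), by = 2)
    a <- matrix(runif(n_points * n_samples), n_points, n_samples,
                dimnames = list(NULL, sprintf("samp%02d", seq_len(n_samples))))
    spectrum_set(w, a)
  })
}

# single synthetic band on a grid, optionally with baseline/noise
band_spectrum <- function(center = 1510, sigma = 10, amplitude = 0.5,
                          wavenumbers = seq(800, 1800, by = 2),
                          noise_sd = 0, baseline = c(0, 0, 0), seed = NULL,
                          sample_id = "b1") {
  bands <- data.frame(name = "x", center = center, sigma = sigma)
  simulate_spectrum(c(x = amplitude), wavenumbers,
    noise_sd = noise_sd,
    baseline_coef = baseline, seed = seed, sample_id = sample_id,
    bands = bands
  )
}

# default preprocessing but without normalization (for absolute-scale
# recovery tests against generator truth)
preprocess_unnormalized <- function(set) {
  preprocess_set(set, preprocess_config(
    normalization = "none",
    replicate_policy = "keep-all"
  ))$set
}
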