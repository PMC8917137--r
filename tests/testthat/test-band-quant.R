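# Oscillator fitting, band areas, profile quantification.

test_that("a noiseless single band is recovered to solver precision", {
  sp <- band_spectrum(center = 1510, sigma = 10, amplitude = 0.5,
                      wavenumbers = seq(1400, 1620, by = 2))
  init <- data.frame(center = 1510 * 1.005, sigma = 11, amplitude = 0.45)
  fit <- fit_oscillators(sp, c(1400, 1620), init)
  expect_true(fit$converged)
  osc <- fit$oscillators
  expect_equal(osc$center, 1510, tolerance = 1e-6)
  expect_equal(osc$sigma, 10, tolerance = 1e-6)
  expect_equal(osc$amplitude, 0.5, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-8)
  # closed-form area of the fitted oscillator
  expect_equal(osc$area, gauss_area(0.5, 10), tolerance = 1e-6)
})

test_that("the fit objective never increases across solver iterations", {
  sp <- band_spectrum(center = 1510, sigma = 10, amplitude = 0.5,
                      noise_sd = 0.01, seed = 3,
                      wavenumbers = seq(1400, 1620, by = 2))
  init <- data.frame(center = 1505, sigma = 14, amplitude = 0.3)
  fit <- fit_oscillators(sp, c(1400, 1620), init)
  expect_true(all(diff(fit$rss_trace) <= 1e-12))
})

test_that("a zero spectrum fits to zero amplitudes", {
  w <- seq(1400, 1620, by = 2)
  sp <- spectrum_set(w, matrix(0, length(w), 1))
  init <- data.frame(center = 1510, sigma = 10, amplitude = 0.1)
  fit <- fit_oscillators(sp, c(1400, 1620), init)
  expect_equal(fit$oscillators$amplitude, 0, tolerance = 1e-10)
  expect_lt(fit$residual_rms, 1e-10)
})

test_that("overlapping bands at SNR 100 are resolved within 5%", {
  w <- seq(1420, 1650, by = 2)
  bands <- data.frame(name = c("lignin", "amide"),
                      center = c(1510, 1550), sigma = c(12, 12))
  sp <- simulate_spectrum(c(lignin = 0.5, amide = 0.4), w,
    noise_sd = 0.005, seed = 21, bands = bands
  )
  init <- data.frame(center = c(1510, 1550), sigma = c(10, 10),
                     amplitude = c(0.3, 0.3))
  fit <- fit_oscillators(sp, c(1420, 1650), init)
  a1 <- band_area(fit, list(name = "lignin", center = 1510))
  a2 <- band_area(fit, list(name = "amide", center = 1550))
  expect_equal(a1, gauss_area(0.5, 12), tolerance = 0.05)
  expect_equal(a2, gauss_area(0.4, 12), tolerance = 0.05)
})

test_that("fitted area equals numerical integration on noiseless input", {
  w <- seq(900, 1500, by = 2)
  sp <- band_spectrum(center = 1200, sigma = 9, amplitude = 0.3,
                      wavenumbers = w)
  init <- data.frame(center = 1198, sigma = 10, amplitude = 0.2)
  fit <- fit_oscillators(sp, c(900, 1500), init)
  area_fit <- band_area(fit, list(name = "Pi", center = 1200))
  area_num <- trapz(w, as.numeric(sp$absorbance))
  expect_equal(area_fit, area_num, tolerance = 5e-3)
})

test_that("band areas scale linearly with amplitude", {
  fit_amp <- function(a) {
    sp <- band_spectrum(amplitude = a, wavenumbers = seq(1400, 1620, 2))
    fit <- fit_oscillators(sp, c(1400, 1620),
      data.frame(center = 1508, sigma = 11, amplitude = a * 0.9)
    )
    band_area(fit, list(name = "lignin", center = 1510))
  }
  expect_equal(fit_amp(0.6), 2 * fit_amp(0.3), tolerance = 1e-6)
})

test_that("matching and precondition errors are typed", {
  sp <- band_spectrum(wavenumbers = seq(1400, 1620, 2))
  init <- data.frame(center = 1510, sigma = 10, amplitude = 0.5)
  fit <- fit_oscillators(sp, c(1400, 1620), init)
  expect_error(band_area(fit, list(name = "lipid", center = 1710)),
               class = "phospec_unmatched_band")
  expect_error(fit_oscillators(sp, c(1400, 1403), init),
               class = "phospec_region_error")
  bad_init <- data.frame(center = 1300, sigma = 10, amplitude = 0.5)
  expect_error(fit_oscillators(sp, c(1400, 1620), bad_init),
               class = "phospec_bounds_error")
})

test_that("profile quantification recovers the generator truth", {
  # one optimal-condition plant, technical noise only
  amps <- unlist(dose_response(500, 6)[1, ])
  sp <- simulate_spectrum(amps, noise_sd = 0.003,
                          baseline_coef = c(0.04, 0.005, 0.006), seed = 31)
  prepped <- preprocess_unnormalized(sp)
  prof <- quantify_profile(prepped)
  expect_true(prof$converged)
  bands <- generator_bands()
  for (nm in c("Pi", "Po", "cellulose", "lignin", "amide", "lipid")) {
    truth_area <- gauss_area(amps[[nm]], bands$sigma[bands$name == nm])
    expect_equal(prof[[nm]], truth_area, tolerance = 0.10, label = nm)
  }
})

test_that("equal cellulose and lignin bands give a unit C/L ratio", {
  bands <- generator_bands()
  bands$sigma[bands$name %in% c("cellulose", "lignin")] <- 10
  sp <- simulate_spectrum(c(cellulose = 0.5, lignin = 0.5, poly = 0.8),
                          noise_sd = 0, bands = bands)
  prof <- quantify_profile(preprocess_unnormalized(sp))
  expect_equal(prof$cl_ratio, 1, tolerance = 0.02)
})

test_that("quantified concentrations are scale-equivariant", {
  amps <- unlist(dose_response(150, 6)[1, ])
  sp <- simulate_spectrum(amps, noise_sd = 0)
  sp3 <- spectrum_set(sp$wavenumbers, sp$absorbance * 3)
  p1 <- quantify_profile(preprocess_unnormalized(sp))
  p3 <- quantify_profile(preprocess_unnormalized(sp3))
  for (nm in c("Pi", "Po", "cellulose", "lignin", "amide", "lipid")) {
    expect_equal(p3[[nm]], 3 * p1[[nm]], tolerance = 1e-3, label = nm)
  }
  # and the C/L ratio is scale-invariant
  expect_equal(p3$cl_ratio, p1$cl_ratio, tolerance = 1e-6)
})

test_that("signature recovery holds across 50 simulated plants", {
  lab <- simulate_lab_dataset(seed = 17)
  sub <- lab$spectra[seq_len(150)]  # 50 plants x 3 technical replicates
  prepped <- preprocess_set(sub, preprocess_config(normalization = "none"))$set
  profiles <- quantify_set(prepped)
  truth <- lab$truth[match(profiles$sample_id, lab$truth$plant_id), ]
  bands <- generator_bands()
  for (nm in c("Pi", "Po", "cellulose", "lignin", "amide", "lipid")) {
    truth_area <- gauss_area(truth[[nm]], bands$sigma[bands$name == nm])
    rel_err <- abs(profiles[[nm]] - truth_area) / truth_area
    expect_lt(median(rel_err), 0.10, label = nm)
  }
})

test_that("the quantified C/L contrast reproduces the 3-fold P response", {
  lab <- simulate_lab_dataset(seed = 1)
  pp <- preprocess_set(lab$spectra)
  keep <- which(pp$set$metadata$series %in% c("P", "shared"))
  prof <- quantify_set(pp$set[keep])
  cl <- tapply(prof$cl_ratio, prof$p_conc, mean)
  fold <- cl[["500"]] / mean(cl[c("1", "10", "30")])
  expect_equal(fold, 3, tolerance = 0.15)
})

test_that("Pi/Po ratio behaves and respects the floor", {
  prof <- data.frame(sample_id = c("a", "b"), Pi = c(1, 4), Po = c(1, 2))
  expect_equal(pi_po_ratio(prof), c(1, 2))
  low <- data.frame(sample_id = "c", Pi = 1, Po = 1e-9)
  expect_error(pi_po_ratio(low), class = "phospec_ratio_floor")
})

test_that("senescence raises the quantified Pi/Po ratio at the high-P site", {
  fld <- simulate_field_dataset(seed = 8)
  ids <- c("high_P_p01_T3", "high_P_p01_T5")
  prepped <- preprocess_set(
    fld$spectra[ids],
    preprocess_config(replicate_policy = "keep-all", normalization = "none")
  )$set
  prof <- quantify_set(prepped)
  ratios <- pi_po_ratio(prof)
  names(ratios) <- prof$sample_id
  expect_gt(ratios[["high_P_p01_T5"]], ratios[["high_P_p01_T3"]])
})
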