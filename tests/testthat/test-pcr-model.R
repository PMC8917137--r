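# Principal-component regression, cross-validated component selection,
# bootstrap training, prediction.

make_lowrank <- function(n, p, r, seed, noise = 0) {
  withr::with_seed(seed, {
    S <- matrix(rnorm(n * r), n, r)
    L <- matrix(rnorm(p * r), p, r)
    beta <- rnorm(r)
    X <- S %*% t(L) + matrix(rnorm(n * p), n, p) * noise
    y <- as.numeric(S %*% beta)
    list(X = X, y = y)
  })
}

test_that("rank-1 noiseless data is fitted exactly with one component", {
  d <- make_lowrank(20, 15, 1, seed = 1)
  m <- fit_pcr(d$X, d$y, 1, target_transform = "identity")
  expect_lt(max(abs(m$residuals)), 1e-10)
  expect_equal(crossprod(m$loadings), diag(1), ignore_attr = TRUE)
})

test_that("full-rank PCR equals the pseudo-inverse least-squares oracle", {
  skip_if_not_installed("MASS")
  for (trial in 1:100) {
    d <- make_lowrank(20, 50, 19, seed = 1000 + trial, noise = 0.3)
    m <- fit_pcr(d$X, d$y, 19, target_transform = "identity")
    # oracle: direct minimum-norm least squares on the centered matrix
    Xc <- sweep(d$X, 2, colMeans(d$X))
    beta <- MASS::ginv(Xc) %*% (d$y - mean(d$y))
    oracle <- mean(d$y) + as.numeric(Xc %*% beta)
    expect_equal(m$fitted, oracle, tolerance = 1e-8)
  }
})

test_that("training rows can be permuted without changing the model", {
  d <- make_lowrank(30, 12, 5, seed = 2, noise = 0.1)
  m1 <- fit_pcr(d$X, d$y, 5, target_transform = "identity")
  perm <- withr::with_seed(9, sample(30))
  m2 <- fit_pcr(d$X[perm, ], d$y[perm], 5, target_transform = "identity")
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
})

test_that("requesting more components than the rank is a typed error", {
  d <- make_lowrank(30, 12, 3, seed = 3)
  expect_error(fit_pcr(d$X, d$y, 8, target_transform = "identity"),
               class = "phospec_rank_error")
})

test_that("cross-validation recovers the true rank of noiseless data", {
  d <- make_lowrank(60, 30, 3, seed = 4)
  cv <- suppressWarnings(
    select_components(d$X, d$y, folds = 10, max_components = 8, seed = 5,
                      target_transform = "identity")
  )
  expect_equal(cv$selected_components, 3)
  # MSEP is non-increasing up to the true rank
  expect_true(all(diff(cv$msep_by_components[1:3]) < 0))
})

test_that("fold assignment and the CV result are seed-reproducible", {
  d <- make_lowrank(50, 20, 4, seed = 6, noise = 0.2)
  cv1 <- select_components(d$X, d$y, folds = 5, max_components = 6, seed = 7,
                           target_transform = "identity")
  cv2 <- select_components(d$X, d$y, folds = 5, max_components = 6, seed = 7,
                           target_transform = "identity")
  expect_identical(cv1, cv2)
})

test_that("the MSEP curve matches a refit-per-fold brute-force oracle", {
  d <- make_lowrank(40, 15, 4, seed = 8, noise = 0.2)
  folds <- 5
  kmax <- 6
  cv <- select_components(d$X, d$y, folds = folds, max_components = kmax,
                          seed = 11, target_transform = "identity")
  fold_id <- phospec:::fold_assignment(seq_len(40), folds, 11)
  sq <- matrix(NA_real_, 40, kmax)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    for (k in seq_len(kmax)) {
      m <- fit_pcr(d$X[tr, ], d$y[tr], k, target_transform = "identity")
      pred <- predict_available(m, d$X[!tr, , drop = FALSE])
      sq[!tr, k] <- (pred - d$y[!tr])^2
    }
  }
  expect_equal(unname(cv$msep_by_components), colMeans(sq), tolerance = 1e-10)
})

test_that("cross-validation never trains on its test fold", {
  # at n = p + 1 a full-rank fit interpolates (memorizes) the training data;
  # honest CV error on random targets must stay far above that
  d <- make_lowrank(12, 11, 11, seed = 12, noise = 1)
  y <- withr::with_seed(13, rnorm(12))
  cv <- suppressWarnings(
    select_components(d$X, y, folds = 6, max_components = 11, seed = 14,
                      target_transform = "identity")
  )
  m <- fit_pcr(d$X, y, 11, target_transform = "identity")
  expect_lt(mean(m$residuals^2), 1e-16)
  expect_gt(min(cv$msep_by_components), 0.01)
})

test_that("predictions are affine-equivariant and honor centering", {
  d <- make_lowrank(25, 10, 4, seed = 15, noise = 0.1)
  m1 <- fit_pcr(d$X, d$y, 4, target_transform = "identity")
  m2 <- fit_pcr(d$X, d$y + 11, 4, target_transform = "identity")
  p1 <- predict_available(m1, d$X)
  p2 <- predict_available(m2, d$X)
  expect_equal(p2, p1 + 11, tolerance = 1e-8)

  # the training-mean spectrum predicts the inverse-transformed intercept
  mu <- matrix(m1$mean_spectrum, 1)
  expect_equal(predict_available(m1, mu), m1$coefficients[1],
               tolerance = 1e-10)
})

test_that("a saturated full-rank fit interpolates its training targets", {
  # 8 rows, centered rank 7: 7 scores + intercept reproduce any target
  X <- withr::with_seed(16, matrix(rnorm(8 * 10), 8, 10))
  y <- withr::with_seed(17, runif(8, 1, 2))
  m <- fit_pcr(X, y, 7, target_transform = "identity")
  expect_equal(predict_available(m, X), y, tolerance = 1e-8)
})

test_that("prediction refuses a mismatched wavenumber grid", {
  lab <- simulate_lab_dataset(seed = 21, n_replicates = 2, dead_low_p = 0)
  pp <- preprocess_set(lab$spectra)$set
  targets <- setNames(lab$truth$p_conc, lab$truth$plant_id)
  fitted <- bootstrap_train(pp, targets, n_resamples = 50,
                            max_components = 5, folds = 5, seed = 1)
  shifted <- spectrum_set(pp$wavenumbers + 1, pp$absorbance, pp$metadata)
  expect_error(predict_available(fitted$model, shifted),
               class = "phospec_grid_mismatch")
  truncated <- restrict_region(pp, 800, 1700)
  expect_error(predict_available(fitted$model, truncated),
               class = "phospec_grid_mismatch")
  # the training grid itself predicts without NAs
  ok <- predict_available(fitted$model, pp)
  expect_false(anyNA(ok$predicted))
})

test_that("the learning curve is the CV curve, capped at the usable rank", {
  d <- make_lowrank(60, 30, 3, seed = 18)
  cv <- suppressWarnings(
    select_components(d$X, d$y, folds = 10, max_components = 8, seed = 19,
                      target_transform = "identity")
  )
  lc <- suppressWarnings(
    learning_curve(d$X, d$y, folds = 10, max_components = 8, seed = 19,
                   target_transform = "identity")
  )
  expect_equal(lc$msep, unname(cv$msep_by_components))
  expect_equal(nrow(lc), length(cv$msep_by_components))
  expect_true(cv$capped)

  d2 <- make_lowrank(50, 20, 6, seed = 20, noise = 0.3)
  lc2 <- learning_curve(d2$X, d2$y, folds = 5, max_components = 6, seed = 3,
                        target_transform = "identity")
  expect_equal(nrow(lc2), 6)
})

test_that("disabling resampling reduces the bootstrap to plain select+fit", {
  lab <- simulate_lab_dataset(seed = 22, n_replicates = 3, dead_low_p = 0)
  pp <- preprocess_set(lab$spectra)$set
  targets <- setNames(lab$truth$p_conc, lab$truth$plant_id)
  n <- n_spectra(pp)
  fitted <- bootstrap_train(pp, targets, n_resamples = n, resample = FALSE,
                            folds = 5, max_components = 8, seed = 30)
  X <- t(pp$absorbance)
  y <- targets[pp$metadata$plant_id]
  cv <- select_components(X, y, folds = 5, max_components = 8, seed = 31,
                          groups = pp$metadata$plant_id)
  direct <- fit_pcr(X, y, cv$selected_components, grid = pp$wavenumbers)
  expect_equal(fitted$cv$msep_by_components, cv$msep_by_components)
  expect_equal(fitted$model$coefficients, direct$coefficients,
               tolerance = 1e-10)
})

test_that("component selection is stable across bootstrap seeds", {
  lab <- simulate_lab_dataset(seed = 1)
  pp <- preprocess_set(lab$spectra)$set
  targets <- setNames(lab$truth$p_conc, lab$truth$plant_id)
  k <- vapply(c(101, 202), function(s) {
    bootstrap_train(pp, targets, n_resamples = 1500, folds = 10,
                    max_components = 20, seed = s)$cv$selected_components
  }, numeric(1))
  expect_lte(abs(diff(k)), 5)
})

test_that("predicted log10 P is unbiased at every design level", {
  errs <- vector("list", 20)
  for (i in 1:20) {
    lab <- simulate_lab_dataset(seed = 400 + i)
    pp <- preprocess_set(lab$spectra)$set
    targets <- setNames(lab$truth$p_conc, lab$truth$plant_id)
    plants <- pp$metadata$plant_id
    test_ids <- withr::with_seed(500 + i, sample(plants, 16))
    tr <- !(plants %in% test_ids)
    m <- fit_pcr(t(pp$absorbance[, tr]), targets[plants[tr]], 8,
                 grid = pp$wavenumbers)
    pred <- predict_available(m, t(pp$absorbance[, !tr, drop = FALSE]))
    errs[[i]] <- data.frame(
      level = targets[plants[!tr]],
      err = log10(pred) - log10(targets[plants[!tr]])
    )
  }
  all_err <- do.call(rbind, errs)
  bias <- tapply(all_err$err, all_err$level, mean)
  expect_true(all(abs(bias) < 0.1))
})

test_that("the model JSON container round-trips", {
  d <- make_lowrank(20, 8, 3, seed = 23, noise = 0.2)
  y <- withr::with_seed(24, runif(20, 10, 500))
  m <- fit_pcr(d$X, y, 3, grid = seq_len(8))
  path <- withr::local_tempfile(fileext = ".json")
  write_pcr_model(m, path)
  back <- read_pcr_model(path)
  expect_equal(back$mean_spectrum, m$mean_spectrum, tolerance = 1e-12)
  expect_equal(back$loadings, m$loadings, tolerance = 1e-12)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(back$training_grid, m$training_grid)
  expect_identical(back$target_transform, m$target_transform)
  expect_equal(predict_available(back, d$X), predict_available(m, d$X),
               tolerance = 1e-10)
  expect_error(read_pcr_model(withr::local_tempfile()),
               class = "phospec_io_error")
})
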