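# Principal-component regression with bootstrap augmentation and 10-fold
# cross-validated component selection.  The decomposition, score regression
# and cross-validation are implemented directly (centering + SVD /
# eigendecomposition of the cross-product, ordinary least squares on the
# orthogonal scores) so the model file is a self-contained text artifact.

pcr_transform <- function(y, transform) {
  switch(transform,
    identity = y,
    log10 = {
      if (any(y <= 0)) {
        ps_error("log10 target transform requires positive targets",
                 "phospec_transform_error")
      }
      log10(y)
    },
    ps_error(sprintf("unknown target transform '%s'", transform),
             "phospec_transform_error")
  )
}

pcr_untransform <- function(y, transform) {
  switch(transform, identity = y, log10 = 10^y)
}

# Leading right singular directions of the centered matrix.  For tall
# matrices the eigendecomposition of the cross-product is used (identical
# subspace, much faster for bootstrap-sized row counts).
pcr_decompose <- function(Xc) {
  if (nrow(Xc) >= ncol(Xc)) {
    e <- eigen(crossprod(Xc), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    v <- e$vectors
  } else {
    s <- svd(Xc, nu = 0)
    v <- s$v
    d <- s$d
  }
  # sign convention: largest-magnitude element of each loading is positive,
  # so the decomposition is invariant to row order and BLAS summation noise
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  list(v = v, d = d)
}

pcr_rank <- function(d) sum(d > max(d[1], .Machine$double.eps) * 1e-8)

#' Fit a principal-component regression
#'
#' Centers the spectra matrix, takes the leading right singular directions
#' as loadings, and regresses the (optionally log10-transformed) target on
#' the component scores by ordinary least squares with an intercept.
#'
#' @param X Numeric matrix, one row per training spectrum (no missing
#'   values).
#' @param y Target vector (medium concentration), length `nrow(X)`.
#' @param n_components Number of components to retain; must not exceed the
#'   rank of the centered matrix.
#' @param target_transform `"log10"` (default; design levels span several
#'   decades) or `"identity"`.
#' @param grid Optional wavenumber grid recorded as `training_grid` and
#'   enforced at prediction time.
#' @return A `pcr_model`: list with `mean_spectrum`, `loadings` (orthonormal
#'   columns), `coefficients` (intercept first), `n_components`,
#'   `target_transform`, `training_grid`, `fitted` and `residuals` (on the
#'   transform scale).
#' @export
fit_pcr <- function(X, y, n_components, target_transform = "log10",
                    grid = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    ps_error("rows of X must match length of y", "phospec_length_mismatch")
  }
  if (anyNA(X) || anyNA(y)) {
    ps_error("X and y must be complete (no missing values)",
             "phospec_nonfinite")
  }
  if (nrow(X) < n_components + 1) {
    ps_error("need at least n_components + 1 training rows",
             "phospec_rank_error")
  }
  yt <- pcr_transform(y, target_transform)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  dec <- pcr_decompose(Xc)
  rk <- pcr_rank(dec$d)
  if (rk < n_components) {
    ps_error(
      sprintf("requested %d components but the centered matrix has rank %d",
              n_components, rk),
      "phospec_rank_error"
    )
  }
  V <- dec$v[, seq_len(n_components), drop = FALSE]
  scores <- Xc %*% V
  fit <- stats::lm.fit(cbind(1, scores), yt)
  structure(
    list(
      mean_spectrum = mu,
      loadings = V,
      coefficients = unname(fit$coefficients),
      n_components = n_components,
      target_transform = target_transform,
      training_grid = grid,
      fitted = unname(fit$fitted.values),
      residuals = unname(fit$residuals)
    ),
    class = "pcr_model"
  )
}

#' @export
#' @method print pcr_model
print.pcr_model <- function(x, ...) {
  cat(sprintf(
    "<pcr_model> %d components, %d-point spectra, %s target, train RMSE %.4g\n",
    x$n_components, length(x$mean_spectrum), x$target_transform,
    sqrt(mean(x$residuals^2))
  ))
  invisible(x)
}

predict_pcr_matrix <- function(model, X, transformed = FALSE) {
  Xc <- sweep(as.matrix(X), 2, model$mean_spectrum)
  scores <- Xc %*% model$loadings
  pred <- as.numeric(cbind(1, scores) %*% model$coefficients)
  if (transformed) pred else pcr_untransform(pred, model$target_transform)
}

#' Predict plant-available concentration for new spectra
#'
#' Projects centered spectra on the training loadings, applies the score
#' regression and inverts the target transform.  The new grid must equal the
#' training grid exactly; use [resample_to_grid()] first if it does not (no
#' silent interpolation).
#'
#' @param model A `pcr_model`.
#' @param newdata A [spectrum_set] on the training grid, or a bare matrix
#'   with one row per spectrum.
#' @return For a set, a `data.frame` of `sample_id`, `predicted` (original
#'   scale, e.g. uM for P) and `predicted_transformed`; for a matrix, the
#'   numeric predictions on the original scale.
#' @export
predict_available <- function(model, newdata) {
  stopifnot(inherits(model, "pcr_model"))
  if (inherits(newdata, "spectrum_set")) {
    if (!is.null(model$training_grid)) {
      g <- newdata$wavenumbers
      tg <- model$training_grid
      if (length(g) != length(tg) || max(abs(g - tg)) > 1e-9) {
        ps_error(
          "spectrum grid differs from the model training grid; resample explicitly with resample_to_grid()",
          "phospec_grid_mismatch"
        )
      }
    }
    X <- t(newdata$absorbance)
    data.frame(
      sample_id = colnames(newdata$absorbance),
      predicted = predict_pcr_matrix(model, X),
      predicted_transformed = predict_pcr_matrix(model, X, transformed = TRUE),
      stringsAsFactors = FALSE
    )
  } else {
    predict_pcr_matrix(model, as.matrix(newdata))
  }
}

fold_assignment <- function(groups, folds, seed) {
  ug <- unique(groups)
  if (length(ug) < folds) {
    ps_error(
      sprintf("%d groups cannot populate %d folds", length(ug), folds),
      "phospec_cv_error"
    )
  }
  shuffled <- with_opt_seed(seed, sample(ug))
  fold_of_group <- stats::setNames(
    rep(seq_len(folds), length.out = length(ug)), shuffled
  )
  unname(fold_of_group[as.character(groups)])
}

#' Select the PCR component count by k-fold cross-validation
#'
#' For every candidate component count up to `max_components`, the mean
#' squared error of prediction (MSEP, on the transform scale) is pooled over
#' the held-out folds; the smallest count achieving the minimum is selected.
#' Rows sharing a group label (e.g. bootstrap copies of one plant) are kept
#' whole within folds so technical or resampling replicates never leak
#' across the train/test split.
#'
#' @param X,y Training matrix and target vector (original scale).
#' @param folds Number of folds (default 10, >= 2).
#' @param max_components Largest component count to try; capped (with a
#'   warning) at the smallest training-fold rank.
#' @param seed Seed for the fold shuffle.
#' @param groups Optional group labels, length `nrow(X)`.
#' @param target_transform As in [fit_pcr()].
#' @return A `cv_result`: list with `msep_by_components` (indexed 1..K),
#'   `selected_components`, `folds`, `seed`, `capped`.
#' @export
select_components <- function(X, y, folds = 10, max_components, seed = 1,
                              groups = NULL, target_transform = "log10") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(folds >= 2, max_components >= 1)
  if (nrow(X) < folds) {
    ps_error("need at least as many rows as folds", "phospec_cv_error")
  }
  if (is.null(groups)) groups <- seq_len(nrow(X))
  yt <- pcr_transform(y, target_transform)
  fold_id <- fold_assignment(groups, folds, seed)
  kmax <- max_components
  fold_dec <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    mu <- colMeans(X[tr, , drop = FALSE])
    Xc <- sweep(X[tr, , drop = FALSE], 2, mu)
    dec <- pcr_decompose(Xc)
    rk <- pcr_rank(dec$d)
    kmax <- min(kmax, rk)
    fold_dec[[f]] <- list(mu = mu, v = dec$v, tr = tr)
  }
  capped <- kmax < max_components
  if (capped) {
    warning(sprintf(
      "max_components reduced from %d to %d (training-fold rank limit)",
      max_components, kmax
    ))
  }
  sq_err <- matrix(0, nrow(X), kmax)
  for (f in seq_len(folds)) {
    fd <- fold_dec[[f]]
    tr <- fd$tr
    V <- fd$v[, seq_len(kmax), drop = FALSE]
    Str <- sweep(X[tr, , drop = FALSE], 2, fd$mu) %*% V
    Ste <- sweep(X[!tr, , drop = FALSE], 2, fd$mu) %*% V
    y_tr <- yt[tr]
    intercept <- mean(y_tr)
    # scores are orthogonal with zero column means, so per-component
    # regression coefficients are independent and predictions accumulate
    gamma <- colSums(Str * (y_tr - intercept)) / colSums(Str^2)
    pred <- intercept + t(apply(
      sweep(Ste, 2, gamma, "*"), 1, cumsum
    ))
    if (kmax == 1) pred <- matrix(pred, ncol = 1)
    sq_err[!tr, ] <- (pred - yt[!tr])^2
  }
  msep <- colMeans(sq_err)
  names(msep) <- seq_len(kmax)
  structure(
    list(
      msep_by_components = msep,
      selected_components = unname(which.min(msep)),
      folds = folds,
      seed = seed,
      capped = capped
    ),
    class = "cv_result"
  )
}

#' @export
#' @method print cv_result
print.cv_result <- function(x, ...) {
  k <- x$selected_components
  cat(sprintf(
    "<cv_result> %d-fold CV over %d component counts: selected %d (MSEP %.4g)\n",
    x$folds, length(x$msep_by_components), k, x$msep_by_components[k]
  ))
  invisible(x)
}

#' MSEP learning curve
#'
#' The cross-validated MSEP as a function of component count, as a table for
#' plotting.  Values are identical to `msep_by_components` of the
#' corresponding [select_components()] result.
#'
#' @inheritParams select_components
#' @return A `data.frame` with columns `n_components` and `msep`.
#' @export
learning_curve <- function(X, y, folds = 10, max_components, seed = 1,
                           groups = NULL, target_transform = "log10") {
  cv <- select_components(X, y,
    folds = folds, max_components = max_components,
    seed = seed, groups = groups, target_transform = target_transform
  )
  data.frame(
    n_components = seq_along(cv$msep_by_components),
    msep = unname(cv$msep_by_components)
  )
}

#' Bootstrap-augmented PCR training
#'
#' Builds a training matrix of `n_resamples` rows by sampling units (plants
#' by default) with replacement from the spectrum set, runs
#' [select_components()] with fold assignment grouped by source unit, and
#' fits the final model at the selected component count.
#'
#' @param set A preprocessed [spectrum_set] (typically replicate-averaged,
#'   one spectrum per plant).
#' @param targets Named numeric vector of medium concentrations keyed by
#'   unit id (plant id or sample id).
#' @param n_resamples Number of bootstrap draws (default 6000).
#' @param unit `"plant"` (resample plants; metadata `plant_id`, falling back
#'   to `sample_id`) or `"spectrum"`.
#' @param folds,max_components,target_transform See [select_components()].
#' @param seed Seed for both the bootstrap draw and the fold shuffle.
#' @param resample Set `FALSE` (with `n_resamples` equal to the number of
#'   units) for the degenerate no-resampling variant, where training reduces
#'   to plain select + fit on the observed units.
#' @return A list with `model` (a `pcr_model`) and `cv` (a `cv_result`).
#' @export
bootstrap_train <- function(set, targets, n_resamples = 6000,
                            unit = c("plant", "spectrum"), folds = 10,
                            max_components = 41, seed = 1,
                            target_transform = "log10", resample = TRUE) {
  stopifnot(inherits(set, "spectrum_set"))
  unit <- match.arg(unit)
  if (n_resamples < folds) {
    ps_error("n_resamples must be at least the number of folds",
             "phospec_cv_error")
  }
  meta <- set$metadata
  unit_ids <- if (unit == "plant" && "plant_id" %in% names(meta)) {
    meta$plant_id
  } else {
    meta$sample_id
  }
  if (anyDuplicated(unit_ids)) {
    ps_error(
      "multiple spectra per unit: average replicates first or use unit = 'spectrum'",
      "phospec_metadata_error"
    )
  }
  missing <- setdiff(unit_ids, names(targets))
  if (length(missing)) {
    ps_error(
      sprintf("no target for unit(s): %s", paste(missing, collapse = ", ")),
      "phospec_metadata_error"
    )
  }
  X <- t(set$absorbance)
  y <- as.numeric(targets[unit_ids])
  n <- length(unit_ids)
  idx <- if (resample) {
    with_opt_seed(seed, sample.int(n, n_resamples, replace = TRUE))
  } else {
    if (n_resamples != n) {
      ps_error("resample = FALSE requires n_resamples == number of units",
               "phospec_cv_error")
    }
    seq_len(n)
  }
  Xb <- X[idx, , drop = FALSE]
  yb <- y[idx]
  gb <- unit_ids[idx]
  cv <- select_components(Xb, yb,
    folds = folds, max_components = max_components,
    seed = seed + 1L, groups = gb, target_transform = target_transform
  )
  model <- fit_pcr(Xb, yb, cv$selected_components,
    target_transform = target_transform, grid = set$wavenumbers
  )
  list(model = model, cv = cv)
}

#' Serialize a PCR model to a JSON text container
#'
#' @param model A `pcr_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pcr_model <- function(model, path) {
  stopifnot(inherits(model, "pcr_model"))
  payload <- list(
    container = "phospec_pcr_model",
    version = 1L,
    n_components = model$n_components,
    target_transform = model$target_transform,
    training_grid = model$training_grid,
    mean_spectrum = model$mean_spectrum,
    coefficients = model$coefficients,
    loadings = model$loadings
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PCR model from its JSON container
#'
#' @param path Path written by [write_pcr_model()].
#' @return A `pcr_model`.
#' @export
read_pcr_model <- function(path) {
  if (!file.exists(path)) {
    ps_error(sprintf("model file not found: %s", path), "phospec_io_error")
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$container, "phospec_pcr_model")) {
    ps_error(sprintf("%s is not a phospec PCR model file", path),
             "phospec_parse_error")
  }
  structure(
    list(
      mean_spectrum = as.numeric(payload$mean_spectrum),
      loadings = matrix(as.numeric(payload$loadings),
        ncol = payload$n_components
      ),
      coefficients = as.numeric(payload$coefficients),
      n_components = as.integer(payload$n_components),
      target_transform = payload$target_transform,
      training_grid = if (is.null(payload$training_grid)) NULL else
        as.numeric(payload$training_grid),
      fitted = NULL,
      residuals = NULL
    ),
    class = "pcr_model"
  )
}
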