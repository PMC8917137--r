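# Baseline correction, max-normalization and technical-replicate
# aggregation.  The pipeline order is fixed: restrict -> baseline ->
# aggregate -> normalize (normalization does not commute with replicate
# averaging unless replicates share a maximum, so the order is part of the
# contract and recorded in the provenance attribute).

#' Preprocessing configuration
#'
#' @param baseline_method `"rubber-band"` (lower convex hull, parameter
#'   free), `"asymmetric-least-squares"` (Eilers-style ALS with smoothness
#'   `als_lambda` and asymmetry `als_p`), or `"polynomial"` (iterative
#'   modified-polynomial fit of degree `poly_degree`).
#' @param poly_degree Polynomial baseline degree (1-6).
#' @param als_lambda,als_p,als_maxit ALS smoothness penalty, asymmetry weight
#'   in (0, 0.5), and iteration cap.
#' @param normalization `"per-spectrum-region-max"` (default; maximum within
#'   `norm_region`), `"per-spectrum-global-max"`, or `"none"`.
#' @param norm_region Region used for region-max normalization, cm^-1.
#' @param replicate_policy `"average"` technical replicates per plant, or
#'   `"keep-all"`.
#' @param region Modeling region the set is restricted to before baseline
#'   correction, half-open `[lo, hi)`.
#' @return A validated list of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_method = "rubber-band",
                              poly_degree = 3,
                              als_lambda = 1e5, als_p = 0.001, als_maxit = 20,
                              normalization = "per-spectrum-region-max",
                              norm_region = c(800, 1800),
                              replicate_policy = "average",
                              region = c(800, 1800)) {
  baseline_method <- match.arg(
    baseline_method,
    c("rubber-band", "asymmetric-least-squares", "polynomial")
  )
  normalization <- match.arg(
    normalization,
    c("per-spectrum-region-max", "per-spectrum-global-max", "none")
  )
  replicate_policy <- match.arg(replicate_policy, c("average", "keep-all"))
  stopifnot(
    poly_degree >= 1, poly_degree <= 6,
    als_lambda > 0, als_p > 0, als_p < 0.5, als_maxit >= 1,
    length(norm_region) == 2, norm_region[1] < norm_region[2],
    length(region) == 2, region[1] < region[2]
  )
  structure(
    list(
      baseline_method = baseline_method, poly_degree = poly_degree,
      als_lambda = als_lambda, als_p = als_p, als_maxit = als_maxit,
      normalization = normalization, norm_region = norm_region,
      replicate_policy = replicate_policy, region = region
    ),
    class = "preprocess_config"
  )
}

# Lower convex hull (Andrew's monotone chain, lower chain only) evaluated on
# the full grid by linear interpolation between hull vertices.
lower_hull_baseline <- function(x, y) {
  n <- length(x)
  idx <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      j <- idx[m]
      k <- idx[m - 1L]
      cr <- (x[j] - x[k]) * (y[i] - y[k]) - (y[j] - y[k]) * (x[i] - x[k])
      if (cr <= 0) m <- m - 1L else break
    }
    m <- m + 1L
    idx[m] <- i
  }
  hull <- idx[seq_len(m)]
  stats::approx(x[hull], y[hull], xout = x)$y
}

# Asymmetric least squares (second-difference penalty, asymmetric weights).
als_baseline <- function(y, lambda, p, maxit) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2, diagonals = list(
    rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2)
  ))
  DtD <- Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(maxit)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(n, w) + lambda * DtD, w * y))
    wnew <- ifelse(y > z, p, 1 - p)
    if (all(wnew == w)) break
    w <- wnew
  }
  z
}

# Iterative modified-polynomial baseline: fit, clip the signal above the fit,
# refit until stable.
poly_baseline <- function(x, y, degree, maxit = 50, tol = 1e-9) {
  xs <- (x - mean(x)) / stats::sd(x)
  X <- vapply(0:degree, function(d) xs^d, numeric(length(xs)))
  yk <- y
  fit <- y
  for (it in seq_len(maxit)) {
    fit <- as.numeric(X %*% qr.coef(qr(X), yk))
    ynew <- pmin(yk, fit)
    if (max(abs(ynew - yk)) < tol) break
    yk <- ynew
  }
  fit
}

baseline_vector <- function(x, y, config) {
  switch(config$baseline_method,
    "rubber-band" = lower_hull_baseline(x, y),
    "asymmetric-least-squares" =
      als_baseline(y, config$als_lambda, config$als_p, config$als_maxit),
    "polynomial" = poly_baseline(x, y, config$poly_degree)
  )
}

#' Baseline-correct a spectrum set
#'
#' Subtracts an estimated smooth baseline from every spectrum.  The
#' rubber-band baseline (lower convex hull) lies at or below the signal by
#' construction; the ALS and polynomial baselines are smooth fits with
#' bounded curvature.
#'
#' @param set A [spectrum_set] with at least 10 grid points.
#' @param config A [preprocess_config()].
#' @return The corrected [spectrum_set].
#' @export
baseline_correct <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "spectrum_set"))
  if (length(set$wavenumbers) < 10) {
    ps_error("baseline correction needs >= 10 grid points",
             "phospec_region_error")
  }
  corrected <- set$absorbance
  for (j in seq_len(ncol(corrected))) {
    corrected[, j] <- corrected[, j] -
      baseline_vector(set$wavenumbers, corrected[, j], config)
  }
  spectrum_set(set$wavenumbers, corrected, set$metadata)
}

#' Normalize spectra to their maximum
#'
#' Scales each spectrum so its maximum over the configured scope equals 1.
#' Point-to-point ratios are preserved.
#'
#' @param set A [spectrum_set].
#' @param scope `"per-spectrum-region-max"`, `"per-spectrum-global-max"`, or
#'   `"none"`.
#' @param region Region for region-max scope, half-open `[lo, hi)` cm^-1.
#' @return The normalized [spectrum_set].
#' @export
normalize_max <- function(set, scope = "per-spectrum-region-max",
                          region = c(800, 1800)) {
  stopifnot(inherits(set, "spectrum_set"))
  scope <- match.arg(
    scope,
    c("per-spectrum-region-max", "per-spectrum-global-max", "none")
  )
  if (scope == "none") {
    return(set)
  }
  keep <- if (scope == "per-spectrum-region-max") {
    set$wavenumbers >= region[1] & set$wavenumbers < region[2]
  } else {
    rep(TRUE, length(set$wavenumbers))
  }
  if (!any(keep)) {
    ps_error("normalization region does not overlap the grid",
             "phospec_empty_region")
  }
  maxima <- apply(set$absorbance[keep, , drop = FALSE], 2, max)
  if (any(maxima <= 0)) {
    bad <- colnames(set$absorbance)[maxima <= 0]
    ps_error(
      sprintf("nonpositive maximum in: %s", paste(bad, collapse = ", ")),
      "phospec_nonpositive_max"
    )
  }
  spectrum_set(
    set$wavenumbers,
    sweep(set$absorbance, 2, maxima, "/"),
    set$metadata
  )
}

#' Aggregate technical replicates
#'
#' With `policy = "average"`, replaces each plant's technical replicates by
#' their pointwise mean (one spectrum per plant, sample id = plant id).  A
#' dispersion table reports the pointwise sample standard deviation of the
#' raw spectra within each condition group.
#'
#' @param set A [spectrum_set] whose metadata carries the replicate grouping.
#' @param policy `"average"` or `"keep-all"`.
#' @param group_col Metadata column identifying the biological unit
#'   (default `"plant_id"`).
#' @param condition_col Metadata column defining dispersion groups (default
#'   `"condition"`; falls back to `group_col` when absent).
#' @return A list with `set` (aggregated or unchanged [spectrum_set]) and
#'   `dispersion` (`data.frame` of wavenumber plus one SD column per
#'   condition).
#' @export
aggregate_replicates <- function(set, policy = "average",
                                 group_col = "plant_id",
                                 condition_col = "condition") {
  stopifnot(inherits(set, "spectrum_set"))
  policy <- match.arg(policy, c("average", "keep-all"))
  meta <- set$metadata
  if (!condition_col %in% names(meta)) {
    condition_col <- if (group_col %in% names(meta)) group_col else "sample_id"
  }
  if (policy == "average" &&
      (!group_col %in% names(meta) || anyNA(meta[[group_col]]))) {
    ps_error(
      sprintf("metadata lacks a complete '%s' grouping column", group_col),
      "phospec_metadata_error"
    )
  }
  conditions <- unique(meta[[condition_col]])
  dispersion <- data.frame(wavenumber = set$wavenumbers)
  for (cond in conditions) {
    members <- which(meta[[condition_col]] == cond)
    dispersion[[as.character(cond)]] <- if (length(members) > 1) {
      apply(set$absorbance[, members, drop = FALSE], 1, stats::sd)
    } else {
      rep(NA_real_, length(set$wavenumbers))
    }
  }
  if (policy == "keep-all") {
    return(list(set = set, dispersion = dispersion))
  }
  groups <- unique(meta[[group_col]])
  mean_mat <- vapply(groups, function(g) {
    members <- which(meta[[group_col]] == g)
    if (length(members) == 0) {
      ps_error(sprintf("replicate group '%s' has no members", g),
               "phospec_metadata_error")
    }
    rowMeans(set$absorbance[, members, drop = FALSE])
  }, numeric(length(set$wavenumbers)))
  mean_mat <- matrix(mean_mat, ncol = length(groups),
                     dimnames = list(NULL, as.character(groups)))
  # keep metadata columns that are constant within every group
  first_rows <- meta[match(groups, meta[[group_col]]), , drop = FALSE]
  constant <- vapply(names(meta), function(cl) {
    all(tapply(meta[[cl]], meta[[group_col]],
               function(v) length(unique(v)) == 1))
  }, logical(1))
  agg_meta <- first_rows[, constant | names(meta) == group_col, drop = FALSE]
  agg_meta$sample_id <- as.character(groups)
  rownames(agg_meta) <- NULL
  list(
    set = spectrum_set(set$wavenumbers, mean_mat, agg_meta),
    dispersion = dispersion
  )
}

#' Run the full preprocessing pipeline
#'
#' Fixed stage order: restrict to the modeling region, baseline-correct each
#' technical spectrum, aggregate replicates, normalize.  The applied order
#' and configuration are recorded in the `provenance` attribute of the
#' returned set.
#'
#' @param set A [spectrum_set] of raw spectra.
#' @param config A [preprocess_config()].
#' @return A list with `set` (processed spectra) and `dispersion` (see
#'   [aggregate_replicates()]).
#' @export
preprocess_set <- function(set, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  out <- restrict_region(set, config$region[1], config$region[2])
  out <- baseline_correct(out, config)
  agg <- aggregate_replicates(out, policy = config$replicate_policy)
  out <- normalize_max(agg$set, scope = config$normalization,
                       region = config$norm_region)
  attr(out, "provenance") <- list(
    order = c("restrict", "baseline", "aggregate", "normalize"),
    config = unclass(config)
  )
  list(set = out, dispersion = agg$dispersion)
}
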