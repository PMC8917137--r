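# Oscillator-model least-squares deconvolution and Beer's-law
# quantification.  Spectra are modelled, region by region, as sums of peaked
# lineshapes; the closed-form area of the oscillator matched to each band
# assignment is taken as proportional to the relative concentration of the
# corresponding chemical species.

#' Default band assignments
#'
#' Biochemical signature bands: organic phosphate (P-O-H / P-O-C
#' deformation) at 980 cm^-1, the broad polysaccharide C-O-C absorption near
#' 1000 cm^-1 on which the phosphate bands sit, cellulose (C-O-C ether) at
#' 1160, inorganic phosphate (P=O stretch) at 1200, lignin (aromatic C=C) at
#' 1510, amide II at 1550, and lipid carbonyl at 1710 cm^-1.  Fit windows
#' group overlapping bands into shared regions: 900-1300 (four oscillators
#' including the broad polysaccharide band), 1450-1620 (lignin + amide) and
#' 1650-1780 (lipid).  Beer coefficients default to 1, giving relative
#' concentrations on the band-area scale.
#'
#' @return A `data.frame` with columns `name`, `center`, `window_lo`,
#'   `window_hi`, `sigma_init`, `sigma_min`, `sigma_max`,
#'   `beer_coefficient`.
#' @export
default_band_assignments <- function() {
  data.frame(
    name       = c("Po", "poly", "cellulose", "Pi", "lignin", "amide", "lipid"),
    center     = c(980,  1000,   1160,        1200, 1510,     1550,    1710),
    window_lo  = c(900,  900,    900,         900,  1450,     1450,    1650),
    window_hi  = c(1300, 1300,   1300,        1300, 1620,     1620,    1780),
    sigma_init = c(9,    60,     10,          9,    9,        10,      11),
    sigma_min  = c(3,    30,     3,           3,    3,        3,       3),
    sigma_max  = c(30,   120,    30,          30,   30,       30,      30),
    beer_coefficient = 1,
    stringsAsFactors = FALSE
  )
}

lineshape_eval <- function(w, center, sigma, amplitude, shape) {
  if (shape == "gaussian") {
    amplitude * exp(-0.5 * ((w - center) / sigma)^2)
  } else if (shape == "lorentzian") {
    amplitude * sigma^2 / ((w - center)^2 + sigma^2)
  } else {
    ps_error(sprintf("unsupported lineshape '%s'", shape),
             "phospec_shape_error")
  }
}

#' Closed-form oscillator area
#'
#' Gaussian: `amplitude * sigma * sqrt(2*pi)`; Lorentzian (half-width
#' `sigma`): `pi * amplitude * sigma`.
#'
#' @param amplitude Peak amplitude (absorbance).
#' @param sigma Width parameter (cm^-1).
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return Area in absorbance * cm^-1.
#' @export
oscillator_area <- function(amplitude, sigma, shape = "gaussian") {
  if (shape == "gaussian") {
    amplitude * sigma * sqrt(2 * pi)
  } else if (shape == "lorentzian") {
    pi * amplitude * sigma
  } else {
    ps_error(sprintf("unsupported lineshape '%s'", shape),
             "phospec_shape_error")
  }
}

as_single_spectrum <- function(x) {
  if (inherits(x, "spectrum_set")) {
    if (ncol(x$absorbance) != 1) {
      ps_error("expected a single spectrum", "phospec_shape_error")
    }
    list(wavenumbers = x$wavenumbers, absorbance = as.numeric(x$absorbance),
         sample_id = colnames(x$absorbance))
  } else {
    stopifnot(is.list(x), !is.null(x$wavenumbers), !is.null(x$absorbance))
    x$sample_id <- x$sample_id %||% "s1"
    x
  }
}

#' Fit an oscillator model to a spectral region
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, via
#' \pkg{minpack.lm}) of a sum of lineshapes against the spectrum restricted
#' to `region` (half-open).  The residual sum of squares is non-increasing
#' across accepted solver steps and is returned as `rss_trace`.
#'
#' @param x A single-sample [spectrum_set] or a list with `wavenumbers` and
#'   `absorbance`.
#' @param region `c(lo, hi)` in cm^-1; must contain at least 3 grid points.
#' @param init `data.frame` with columns `center`, `sigma`, `amplitude` (one
#'   row per oscillator) and optionally `shape`.
#' @param lower,upper Optional bound `data.frame`s with the same columns;
#'   defaults: centers within `center_slack` of their start, sigma in
#'   `[1, region width]`, amplitude in `[0, 10 * max |y|]`.
#' @param center_slack Default half-width of the center bounds (cm^-1).
#' @param max_iter Solver iteration cap; exhausting it sets
#'   `converged = FALSE`.
#' @param local_baseline `"none"` (default), `"constant"` or `"linear"`:
#'   adds a free local baseline term to the window model, absorbing any
#'   residual offset left by the global baseline correction.
#' @return A `peak_fit` object: list with `oscillators` (fitted parameters
#'   plus closed-form `area`), `local_baseline` coefficients,
#'   `residual_rms`, `converged`, `region`, `rss_trace`, `niter`.
#' @export
fit_oscillators <- function(x, region, init, lower = NULL, upper = NULL,
                            center_slack = 15, max_iter = 300,
                            local_baseline = c("none", "constant", "linear")) {
  local_baseline <- match.arg(local_baseline)
  sp <- as_single_spectrum(x)
  stopifnot(length(region) == 2, region[1] < region[2], nrow(init) >= 1)
  keep <- sp$wavenumbers >= region[1] & sp$wavenumbers < region[2]
  if (sum(keep) < 3) {
    ps_error("fit region contains fewer than 3 grid points",
             "phospec_region_error")
  }
  w <- sp$wavenumbers[keep]
  y <- sp$absorbance[keep]
  if (!all(is.finite(y))) {
    ps_error("non-finite absorbance in fit region", "phospec_nonfinite")
  }
  if (any(init$center < region[1] | init$center >= region[2])) {
    ps_error("initial oscillator centers must lie inside the fit region",
             "phospec_bounds_error")
  }
  k <- nrow(init)
  shape <- if ("shape" %in% names(init)) init$shape else rep("gaussian", k)
  amp_cap <- max(10 * max(abs(y)), 10 * max(init$amplitude), 1e-6)
  if (is.null(lower)) {
    lower <- data.frame(center = init$center - center_slack,
                        sigma = rep(1, k), amplitude = rep(0, k))
  }
  if (is.null(upper)) {
    upper <- data.frame(center = init$center + center_slack,
                        sigma = rep(region[2] - region[1], k),
                        amplitude = rep(amp_cap, k))
  }
  nb <- switch(local_baseline, none = 0L, constant = 1L, linear = 2L)
  yspan <- max(max(abs(y)), 1e-6)
  pack <- function(d) c(d$center, d$sigma, d$amplitude)
  p0 <- c(pack(init), rep(0, nb))
  lo <- c(pack(lower), rep(-yspan, nb))
  hi <- c(pack(upper), rep(yspan, nb))
  if (any(!is.finite(lo)) || any(!is.finite(hi))) {
    ps_error("bounds must be finite", "phospec_bounds_error")
  }
  if (any(p0 < lo) || any(p0 > hi)) {
    ps_error("initial oscillator parameters lie outside the bounds",
             "phospec_bounds_error")
  }
  wmid <- mean(range(w))
  wscale <- max(diff(range(w)) / 2, 1)
  model_eval <- function(par) {
    centers <- par[seq_len(k)]
    sigmas <- par[k + seq_len(k)]
    amps <- par[2 * k + seq_len(k)]
    out <- numeric(length(w))
    for (i in seq_len(k)) {
      out <- out + lineshape_eval(w, centers[i], sigmas[i], amps[i], shape[i])
    }
    if (nb >= 1) out <- out + par[3 * k + 1]
    if (nb >= 2) out <- out + par[3 * k + 2] * (w - wmid) / wscale
    out
  }
  fit <- minpack.lm::nls.lm(
    par = p0,
    lower = lo, upper = hi,
    fn = function(par) model_eval(par) - y,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-14, ptol = 1e-14, gtol = 0
    )
  )
  par <- fit$par
  osc <- data.frame(
    center = par[seq_len(k)],
    sigma = par[k + seq_len(k)],
    amplitude = par[2 * k + seq_len(k)],
    shape = shape,
    stringsAsFactors = FALSE
  )
  osc$area <- mapply(oscillator_area, osc$amplitude, osc$sigma, osc$shape)
  structure(
    list(
      oscillators = osc,
      local_baseline = if (nb > 0) par[3 * k + seq_len(nb)] else numeric(0),
      residual_rms = sqrt(mean(fit$fvec^2)),
      converged = fit$info %in% 1:4,
      region = region,
      rss_trace = as.numeric(fit$rsstrace),
      niter = fit$niter,
      sample_id = sp$sample_id
    ),
    class = "peak_fit"
  )
}

#' @export
#' @method print peak_fit
print.peak_fit <- function(x, ...) {
  cat(sprintf(
    "<peak_fit> region [%g, %g), %d oscillators, residual RMS %.3g, %s\n",
    x$region[1], x$region[2], nrow(x$oscillators), x$residual_rms,
    if (x$converged) "converged" else "NOT converged"
  ))
  print(x$oscillators, digits = 4)
  invisible(x)
}

#' Area of the fitted oscillator matched to a band assignment
#'
#' Matches the fitted oscillator nearest to the assignment center (within
#' `tol` cm^-1) and returns its closed-form lineshape area.
#'
#' @param fit A `peak_fit` from [fit_oscillators()].
#' @param assignment One row of a band-assignment table (needs `name` and
#'   `center`).
#' @param tol Matching tolerance, cm^-1 (default 15).
#' @return Area in absorbance * cm^-1.
#' @export
band_area <- function(fit, assignment, tol = 15) {
  stopifnot(inherits(fit, "peak_fit"))
  d <- abs(fit$oscillators$center - assignment$center)
  i <- which.min(d)
  if (d[i] > tol) {
    ps_error(
      sprintf("no fitted oscillator within %g cm^-1 of band '%s' (%g cm^-1)",
              tol, assignment$name, assignment$center),
      "phospec_unmatched_band"
    )
  }
  fit$oscillators$area[i]
}

# Initial amplitude: local signal height at the band center above the window
# minimum, floored at a small positive value.
init_amplitude <- function(w, y, center) {
  max(y[which.min(abs(w - center))] - min(y), 1e-4)
}

#' Quantify a biochemical profile from one spectrum
#'
#' Runs one oscillator fit per congested fit window (windows shared between
#' overlapping assignments), converts matched band areas to relative
#' concentrations through the Beer coefficients, and computes the
#' cellulose/lignin ratio.
#'
#' @param x A single-sample preprocessed [spectrum_set] (baseline-corrected).
#' @param assignments Band-assignment table, default
#'   [default_band_assignments()].
#' @param lignin_floor `cl_ratio` is reported as `NA` when the lignin
#'   relative concentration falls below this floor.
#' @param match_tol Band matching tolerance passed to [band_area()].
#' @param max_iter Solver iteration cap per window.
#' @param local_baseline Per-window baseline term (see [fit_oscillators()]);
#'   `"linear"` by default, which absorbs the small residual offset a
#'   global rubber-band correction leaves on noisy spectra.
#' @return One-row `data.frame`: `sample_id`, one column per signature
#'   (relative concentration), `cl_ratio`, `residual_rms` (worst window),
#'   `converged` (all windows).
#' @export
quantify_profile <- function(x, assignments = default_band_assignments(),
                             lignin_floor = 1e-6, match_tol = 15,
                             max_iter = 300, local_baseline = "linear") {
  sp <- as_single_spectrum(x)
  windows <- unique(assignments[, c("window_lo", "window_hi")])
  conc <- stats::setNames(numeric(nrow(assignments)), assignments$name)
  worst_rms <- 0
  all_conv <- TRUE
  for (r in seq_len(nrow(windows))) {
    region <- c(windows$window_lo[r], windows$window_hi[r])
    members <- assignments[
      assignments$window_lo == region[1] & assignments$window_hi == region[2], ,
      drop = FALSE
    ]
    keep <- sp$wavenumbers >= region[1] & sp$wavenumbers < region[2]
    w <- sp$wavenumbers[keep]
    y <- sp$absorbance[keep]
    init <- data.frame(
      center = members$center,
      sigma = members$sigma_init,
      amplitude = vapply(members$center, function(cc) init_amplitude(w, y, cc),
                         numeric(1))
    )
    lower <- data.frame(center = members$center - match_tol,
                        sigma = members$sigma_min,
                        amplitude = rep(0, nrow(members)))
    upper <- data.frame(center = members$center + match_tol,
                        sigma = members$sigma_max,
                        amplitude = rep(
                          max(10 * max(abs(y)), 10 * init$amplitude, 1e-6),
                          nrow(members)
                        ))
    fit <- tryCatch(
      fit_oscillators(sp, region, init, lower, upper, max_iter = max_iter,
                      local_baseline = local_baseline),
      error = function(e) {
        ps_error(
          sprintf("fit failed for bands [%s] in [%g, %g): %s",
                  paste(members$name, collapse = ", "),
                  region[1], region[2], conditionMessage(e)),
          "phospec_fit_error"
        )
      }
    )
    worst_rms <- max(worst_rms, fit$residual_rms)
    all_conv <- all_conv && fit$converged
    for (b in seq_len(nrow(members))) {
      conc[members$name[b]] <-
        band_area(fit, members[b, ], tol = match_tol) *
        members$beer_coefficient[b]
    }
  }
  cl <- if (conc[["lignin"]] >= lignin_floor) {
    conc[["cellulose"]] / conc[["lignin"]]
  } else {
    NA_real_
  }
  out <- data.frame(sample_id = sp$sample_id, stringsAsFactors = FALSE)
  for (nm in names(conc)) out[[nm]] <- conc[[nm]]
  out$cl_ratio <- cl
  out$residual_rms <- worst_rms
  out$converged <- all_conv
  out
}

#' Quantify profiles for every spectrum in a set
#'
#' @param set A preprocessed [spectrum_set].
#' @param ... Passed to [quantify_profile()].
#' @return A `data.frame` with one row per sample, joined with the set
#'   metadata.
#' @export
quantify_set <- function(set, ...) {
  stopifnot(inherits(set, "spectrum_set"))
  rows <- lapply(seq_len(ncol(set$absorbance)), function(j) {
    quantify_profile(set[j], ...)
  })
  profiles <- do.call(rbind, rows)
  merge(profiles, set$metadata, by = "sample_id", sort = FALSE)
}

#' Inorganic-to-organic phosphate ratio
#'
#' @param profile A profile `data.frame` (rows from [quantify_profile()]) or
#'   any data frame with `Pi` and `Po` columns.
#' @param floor Error when any `Po` falls below this floor.
#' @return Numeric vector `Pi / Po`.
#' @export
pi_po_ratio <- function(profile, floor = 1e-6) {
  stopifnot(all(c("Pi", "Po") %in% names(profile)))
  if (any(profile$Po < floor)) {
    ps_error(
      sprintf("Po below the %g floor for: %s", floor,
              paste(profile$sample_id[profile$Po < floor], collapse = ", ")),
      "phospec_ratio_floor"
    )
  }
  profile$Pi / profile$Po
}
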