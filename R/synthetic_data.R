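# Forward model for leaf ATR-FTIR spectra under nutrient-limitation designs.
#
# The generator emulates two study designs: (a) a sand-culture dose-response
# experiment with five phosphorus levels (1, 10, 30, 150, 500 uM at optimal
# 6 mM N) and five nitrogen levels (0.01, 0.1, 0.3, 1.5, 6 mM at optimal
# 500 uM P), sharing the optimal condition, 9 replicate plants per condition
# with 3 deaths at the lowest P level, and triplicate technical spectra per
# plant; (b) a two-site field season, 30 plants per site sampled at five
# timepoints through senescence.

#' Default wavenumber grid
#'
#' 600-4000 cm^-1 at 2 cm^-1 spacing (1701 points), consistent with a
#' 4 cm^-1 instrument resolution.
#' @return Numeric vector of wavenumbers.
#' @export
default_wavenumbers <- function() seq(600, 4000, by = 2)

#' Generator band table
#'
#' Gaussian oscillators used by the forward model: organic phosphate
#' (P-O-H / P-O-C deformation, ~980 cm^-1), the broad polysaccharide C-O-C
#' absorption (~1000 cm^-1), cellulose (C-O-C ether, ~1160), inorganic
#' phosphate (P=O stretch, ~1200), lignin (aromatic C=C, ~1510), amide II
#' (~1550) and lipid carbonyl (~1710).
#'
#' @return A `data.frame` with columns `name`, `center` (cm^-1) and `sigma`
#'   (Gaussian width parameter, cm^-1).
#' @export
generator_bands <- function() {
  data.frame(
    name   = c("Po", "poly", "cellulose", "Pi", "lignin", "amide", "lipid"),
    center = c(980,  1000,   1160,        1200, 1510,     1550,    1710),
    sigma  = c(9,    60,     10,          9,    9,        10,      11),
    stringsAsFactors = FALSE
  )
}

#' Lab design conditions
#' @return A `data.frame` of the 9 unique nutrient conditions (the optimal
#'   condition 500 uM P / 6 mM N belongs to both series and appears once,
#'   labelled `"shared"`).
#' @export
design_conditions <- function() {
  p_levels <- c(1, 10, 30, 150, 500)
  n_levels <- c(0.01, 0.1, 0.3, 1.5, 6)
  cond <- rbind(
    data.frame(series = "P", p_conc = p_levels, n_conc = 6),
    data.frame(series = "N", p_conc = 500, n_conc = n_levels[n_levels < 6])
  )
  cond$series[cond$p_conc == 500 & cond$n_conc == 6] <- "shared"
  cond$condition <- sprintf("P%g_N%g", cond$p_conc, cond$n_conc)
  cond
}

#' Enumerate the lab sand-culture design
#'
#' One record per surviving plant: 9 conditions x `n_replicates`, minus
#' `dead_low_p` plants removed from the lowest-P condition (the plants that
#' died before harvest).
#'
#' @param n_replicates Replicate plants per condition (default 9).
#' @param dead_low_p Number of dead plants removed at the lowest P level
#'   (default 3; set 0 to keep the full factorial).
#' @param conditions Condition table, defaulting to [design_conditions()];
#'   pass a subset for degenerate designs.
#' @return A `data.frame` with one row per plant: `plant_id`, `series`,
#'   `p_conc` (uM), `n_conc` (mM), `condition`.
#' @export
make_design <- function(n_replicates = 9, dead_low_p = 3,
                        conditions = design_conditions()) {
  stopifnot(n_replicates >= 1, dead_low_p >= 0)
  design <- conditions[rep(seq_len(nrow(conditions)), each = n_replicates), ]
  design$replicate <- rep(seq_len(n_replicates), times = nrow(conditions))
  rownames(design) <- NULL
  if (dead_low_p > 0) {
    low_p <- min(design$p_conc)
    at_low <- which(design$p_conc == low_p)
    if (dead_low_p > length(at_low)) {
      ps_error("more dead plants than replicates at the lowest P level",
               "phospec_design_error")
    }
    design <- design[-utils::tail(at_low, dead_low_p), ]
  }
  design$plant_id <- sprintf("plant%03d", seq_len(nrow(design)))
  rownames(design) <- NULL
  design[, c("plant_id", "series", "p_conc", "n_conc", "condition", "replicate")]
}

# --- dose-response parameterization ---------------------------------------

# Tunables for the latent amplitude curves.  Shapes are piecewise-smooth
# saturating curves in log10 concentration; the cellulose low-P plateau
# (c_lo) is calibrated at run time so the cellulose/lignin amplitude ratio at
# 500 uM P is exactly `cl_fold` times its mean over the sub-150 uM levels.
dr_params <- function() {
  list(
    lp_max = log10(500),
    cell_mid = log10(65), cell_scale = 0.18, cell_amp = 0.85,
    lig_hi = 0.55, lig_drop = 0.25,
    pi0 = 0.06, pi_gain = 0.30,
    po0 = 0.10, po_gain = 0.22,
    lip0 = 0.14, lip_p = 0.18, lip_n = 0.06,
    am0 = 0.18, am_n = 0.30, am_stress = 0.12, am_stress_scale = 0.45,
    poly0 = 0.70, poly_gain = 0.25,
    cl_fold = 3,
    n_ref = 0.01, n_span = log10(600)
  )
}

cellulose_shape <- function(p, c_lo, par) {
  c_lo + (1 - c_lo) * stats::plogis((log10(p) - par$cell_mid) / par$cell_scale)
}

lignin_level <- function(p, par) {
  par$lig_hi - par$lig_drop * (log10(p) / par$lp_max)
}

calibrate_c_lo <- function(par) {
  gap <- function(c_lo) {
    low <- c(1, 10, 30)
    num <- cellulose_shape(500, c_lo, par) / lignin_level(500, par)
    den <- mean(cellulose_shape(low, c_lo, par) / lignin_level(low, par))
    num / den - par$cl_fold
  }
  stats::uniroot(gap, c(0.02, 0.98), tol = 1e-12)$root
}

#' Latent band amplitudes as a function of medium P and N
#'
#' Deterministic dose-response curves encoding the qualitative behaviour of
#' leaf chemistry under nutrient limitation: cellulose rises with P with a
#' threshold jump between 30 and 150 uM; lignin declines gradually with P;
#' lipid and amide are elevated under severe P starvation; inorganic (Pi) and
#' organic (Po) phosphate signatures increase with P; amide and lipid
#' increase with N.  The cellulose curve is calibrated so the implied
#' cellulose/lignin amplitude ratio at 500 uM P is exactly 3x its mean over
#' the 1-30 uM conditions.
#'
#' @param p_conc Medium phosphorus, uM (vectorized).
#' @param n_conc Medium nitrogen, mM (vectorized, recycled).
#' @param par Curve parameter list, see `phospec:::dr_params`.
#' @return A `data.frame` with one row per input and columns `cellulose`,
#'   `lignin`, `lipid`, `amide`, `Pi`, `Po`, `poly` (nonnegative band
#'   amplitudes, absorbance units).
#' @export
dose_response <- function(p_conc, n_conc, par = dr_params()) {
  if (any(!is.finite(p_conc)) || any(!is.finite(n_conc)) ||
      any(p_conc <= 0) || any(n_conc <= 0)) {
    ps_error("concentrations must be positive and finite",
             "phospec_concentration_error")
  }
  k <- max(length(p_conc), length(n_conc))
  p <- rep_len(p_conc, k)
  n <- rep_len(n_conc, k)
  u <- log10(p) / par$lp_max
  ln <- log10(n / par$n_ref) / par$n_span
  c_lo <- calibrate_c_lo(par)
  cs <- cellulose_shape(p, c_lo, par)
  data.frame(
    cellulose = par$cell_amp * cs,
    lignin = lignin_level(p, par),
    lipid = par$lip0 + par$lip_p * (1 - u) + par$lip_n * ln,
    amide = par$am0 + par$am_n * ln +
      par$am_stress * exp(-(log10(p) / par$am_stress_scale)^2),
    Pi = par$pi0 + par$pi_gain * u,
    Po = par$po0 + par$po_gain * u,
    poly = par$poly0 + par$poly_gain * cs
  )
}

# --- spectrum synthesis ----------------------------------------------------

gaussian_profile_matrix <- function(wavenumbers, bands) {
  G <- vapply(seq_len(nrow(bands)), function(i) {
    exp(-0.5 * ((wavenumbers - bands$center[i]) / bands$sigma[i])^2)
  }, numeric(length(wavenumbers)))
  G <- matrix(G, ncol = nrow(bands), dimnames = list(NULL, bands$name))
  G
}

eval_baseline <- function(wavenumbers, coef) {
  t <- (wavenumbers - 2300) / 1000
  coef[1] + coef[2] * t + coef[3] * t^2
}

random_baseline_coef <- function(n) {
  cbind(
    stats::runif(n, 0.02, 0.06),
    stats::runif(n, -0.01, 0.01),
    stats::runif(n, 0, 0.01)
  )
}

#' Simulate one absorbance spectrum
#'
#' Sum of Gaussian oscillator lineshapes at the generator band centers, plus
#' a smooth quadratic baseline and i.i.d. Gaussian noise on absorbance.
#'
#' @param amplitudes Named numeric vector of band amplitudes; names must be a
#'   subset of `generator_bands()$name`.  Unnamed bands are silent.
#' @param wavenumbers Grid, default [default_wavenumbers()].
#' @param noise_sd Standard deviation of additive noise, absorbance units
#'   (>= 0).
#' @param baseline_coef Length-3 numeric `(b0, b1, b2)` of the quadratic
#'   baseline `b0 + b1 t + b2 t^2` with `t = (wavenumber - 2300)/1000`.
#' @param seed Optional RNG seed for the noise draw.
#' @param sample_id Sample id of the returned one-spectrum set.
#' @param bands Band table, default [generator_bands()].
#' @return A single-sample [spectrum_set].
#' @export
simulate_spectrum <- function(amplitudes, wavenumbers = default_wavenumbers(),
                              noise_sd = 0.003, baseline_coef = c(0, 0, 0),
                              seed = NULL, sample_id = "s1",
                              bands = generator_bands()) {
  if (length(wavenumbers) == 0) {
    ps_error("wavenumber grid is empty", "phospec_empty_grid")
  }
  stopifnot(noise_sd >= 0)
  amplitudes <- unlist(amplitudes)
  if (is.null(names(amplitudes)) ||
      !all(names(amplitudes) %in% bands$name)) {
    ps_error("amplitudes must be named after generator bands",
             "phospec_band_error")
  }
  if (any(amplitudes < 0)) {
    ps_error("band amplitudes must be nonnegative", "phospec_band_error")
  }
  a <- stats::setNames(numeric(nrow(bands)), bands$name)
  a[names(amplitudes)] <- amplitudes
  G <- gaussian_profile_matrix(wavenumbers, bands)
  signal <- as.numeric(G %*% a) + eval_baseline(wavenumbers, baseline_coef)
  noise <- with_opt_seed(seed, stats::rnorm(length(wavenumbers), 0, noise_sd))
  spectrum_set(wavenumbers, matrix(signal + noise,
    ncol = 1,
    dimnames = list(NULL, sample_id)
  ))
}

amplitude_names <- c("cellulose", "lignin", "lipid", "amide", "Pi", "Po", "poly")

#' Simulate the full lab dose-response dataset
#'
#' Generates triplicate technical spectra for every surviving plant in the
#' sand-culture design, with plant-level biological variation (independent
#' lognormal multiplicative factors on the latent band amplitudes), a random
#' smooth baseline per technical replicate, and additive measurement noise.
#' The latent ground truth is retained for recovery tests.
#'
#' @param seed RNG seed; identical seeds yield bit-identical datasets.
#' @param n_replicates,dead_low_p Passed to [make_design()].
#' @param tech_reps Technical spectra per plant (default 3).
#' @param noise_sd Additive noise SD, absorbance units.
#' @param plant_sdlog SD (log scale) of the per-plant lognormal amplitude
#'   factors.
#' @param random_baseline Draw a random quadratic baseline per spectrum; if
#'   `FALSE`, baselines are zero.
#' @param wavenumbers Grid.
#' @return A list: `spectra` (a [spectrum_set], one column per technical
#'   spectrum, metadata with `plant_id`, `replicate`, condition fields) and
#'   `truth` (one row per plant with the design, latent amplitudes and
#'   `true_cl_ratio` = cellulose amplitude / lignin amplitude).
#' @export
simulate_lab_dataset <- function(seed = 1, n_replicates = 9, dead_low_p = 3,
                                 tech_reps = 3, noise_sd = 0.003,
                                 plant_sdlog = 0.05, random_baseline = TRUE,
                                 wavenumbers = default_wavenumbers()) {
  with_opt_seed(seed, {
    design <- make_design(n_replicates = n_replicates, dead_low_p = dead_low_p)
    np <- nrow(design)
    base_amp <- as.matrix(dose_response(design$p_conc, design$n_conc))
    noise_fac <- matrix(
      exp(stats::rnorm(np * length(amplitude_names), 0, plant_sdlog)),
      nrow = np
    )
    amp <- base_amp[, amplitude_names, drop = FALSE] * noise_fac
    truth <- cbind(
      design,
      as.data.frame(amp),
      true_cl_ratio = amp[, "cellulose"] / amp[, "lignin"]
    )
    bands <- generator_bands()
    G <- gaussian_profile_matrix(wavenumbers, bands)
    n_spec <- np * tech_reps
    spec_plant <- rep(seq_len(np), each = tech_reps)
    signal <- G %*% t(amp[spec_plant, bands$name, drop = FALSE])
    bl_coef <- if (random_baseline) {
      random_baseline_coef(n_spec)
    } else {
      matrix(0, n_spec, 3)
    }
    for (j in seq_len(n_spec)) {
      signal[, j] <- signal[, j] + eval_baseline(wavenumbers, bl_coef[j, ])
    }
    signal <- signal +
      matrix(stats::rnorm(length(signal), 0, noise_sd), nrow(signal))
    ids <- sprintf(
      "%s_r%d", design$plant_id[spec_plant],
      rep(seq_len(tech_reps), times = np)
    )
    colnames(signal) <- ids
    meta <- cbind(
      data.frame(sample_id = ids, stringsAsFactors = FALSE),
      design[spec_plant, c("plant_id", "series", "p_conc", "n_conc", "condition")],
      replicate = rep(seq_len(tech_reps), times = np)
    )
    rownames(meta) <- NULL
    list(spectra = spectrum_set(wavenumbers, signal, meta), truth = truth)
  })
}

# --- field scenario ---------------------------------------------------------

# Site/season modifiers.  Rows are timepoints T1..T5.  `site_effect` scales
# every between-site difference; at 0 the two sites are exchangeable.
field_params <- function(site_effect = 1) {
  se <- site_effect
  list(
    season_p_mult = c(0.60, 0.80, 1.00, 1.25, 0.50),
    site_p_mean = c(low_P = 150 * (1 - 0.25 * se), high_P = 150 * (1 + 0.25 * se)),
    p_sdlog = 0.15,
    pi_mult = rbind(
      low_P  = c(0.70, 0.85, 0.95, 1.10, 1.20) + se * c(0, -0.05, 0, 0, 0),
      high_P = c(0.70, 0.85, 0.95, 1.10, 1.20) + se * c(0, 0.05, 0.05, 0.05, 0.40)
    ),
    po_mult = rbind(
      low_P  = c(0.75, 0.90, 1.05, 1.10, 1.00),
      high_P = c(0.75, 0.90, 1.05, 1.10, 1.00) + se * c(0, 0, 0, 0, -0.35)
    ),
    cellulose_mult = c(1.15, 1.05, 0.95, 0.85, 0.75),
    lignin_mult = c(0.90, 0.95, 1.00, 1.05, 1.10),
    n_conc_mM = 1.5,
    biomass_base = 60, biomass_gain = 90, biomass_sd = 12
  )
}

#' Simulate the two-site field season
#'
#' Two sites (`low_P`, `high_P`) x `n_plants` plants x five timepoints
#' (T1 early vegetative .. T5 senescence), one spectrum per plant-timepoint.
#' The latent plant-available P rises to a maximum at T4 and drops at
#' senescence; leaf Pi rises through the season and spikes at T5 at the
#' high-P site while Po plateaus near T4 and declines at T5 there; the
#' cellulose/lignin ratio declines as plants mature and is higher at the
#' high-P site.  Second-year biomass is a monotone function of each plant's
#' senescence Pi/Po amplitude ratio plus noise.
#'
#' @param seed RNG seed.
#' @param n_plants Plants per site (default 30).
#' @param site_effect Scales all between-site differences (default 1; 0 makes
#'   the sites exchangeable).
#' @param plant_sdlog Lognormal SD of plant-level amplitude variation.
#' @param noise_sd Additive spectral noise SD.
#' @param random_baseline Random quadratic baseline per spectrum.
#' @param wavenumbers Grid.
#' @return A list: `spectra` (one column per plant-timepoint) and `plants`
#'   (one row per plant-timepoint with `site`, `plant_id`, `timepoint`,
#'   `latent_available_P` (uM), latent amplitudes, `true_pi_po`, and the
#'   per-plant `second_year_biomass` in grams).
#' @export
simulate_field_dataset <- function(seed = 1, n_plants = 30, site_effect = 1,
                                   plant_sdlog = 0.12, noise_sd = 0.003,
                                   random_baseline = TRUE,
                                   wavenumbers = default_wavenumbers()) {
  with_opt_seed(seed, {
    fp <- field_params(site_effect)
    sites <- c("low_P", "high_P")
    tps <- paste0("T", 1:5)
    tab <- expand.grid(
      timepoint = tps, plant = seq_len(n_plants), site = sites,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    tab$plant_id <- sprintf("%s_p%02d", tab$site, tab$plant)
    ti <- match(tab$timepoint, tps)
    nr <- nrow(tab)
    latent_p <- fp$site_p_mean[tab$site] * fp$season_p_mult[ti] *
      exp(stats::rnorm(nr, 0, fp$p_sdlog))
    base_amp <- as.matrix(dose_response(latent_p, fp$n_conc_mM))
    fac <- matrix(exp(stats::rnorm(nr * length(amplitude_names), 0, plant_sdlog)),
                  nrow = nr)
    amp <- base_amp[, amplitude_names, drop = FALSE] * fac
    si <- match(tab$site, rownames(fp$pi_mult))
    amp[, "Pi"] <- amp[, "Pi"] * fp$pi_mult[cbind(si, ti)]
    amp[, "Po"] <- amp[, "Po"] * fp$po_mult[cbind(si, ti)]
    amp[, "cellulose"] <- amp[, "cellulose"] * fp$cellulose_mult[ti]
    amp[, "lignin"] <- amp[, "lignin"] * fp$lignin_mult[ti]
    pi_po <- amp[, "Pi"] / amp[, "Po"]
    # per-plant biomass driven by the senescence-time Pi/Po ratio
    t5 <- tab$timepoint == "T5"
    biomass_t5 <- stats::setNames(
      fp$biomass_base + fp$biomass_gain * pi_po[t5] +
        stats::rnorm(sum(t5), 0, fp$biomass_sd),
      tab$plant_id[t5]
    )
    biomass <- as.numeric(biomass_t5[tab$plant_id])
    ids <- sprintf("%s_%s", tab$plant_id, tab$timepoint)
    bands <- generator_bands()
    G <- gaussian_profile_matrix(wavenumbers, bands)
    signal <- G %*% t(amp[, bands$name, drop = FALSE])
    bl_coef <- if (random_baseline) random_baseline_coef(nr) else matrix(0, nr, 3)
    for (j in seq_len(nr)) {
      signal[, j] <- signal[, j] + eval_baseline(wavenumbers, bl_coef[j, ])
    }
    signal <- signal +
      matrix(stats::rnorm(length(signal), 0, noise_sd), nrow(signal))
    colnames(signal) <- ids
    plants <- cbind(
      data.frame(
        sample_id = ids, site = tab$site, plant_id = tab$plant_id,
        timepoint = tab$timepoint,
        latent_available_P = as.numeric(latent_p),
        stringsAsFactors = FALSE
      ),
      as.data.frame(amp),
      true_pi_po = pi_po,
      second_year_biomass = biomass
    )
    rownames(plants) <- NULL
    meta <- plants[, c("sample_id", "site", "plant_id", "timepoint")]
    list(spectra = spectrum_set(wavenumbers, signal, meta), plants = plants)
  })
}
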