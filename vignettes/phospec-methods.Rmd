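---
title: "Leaf infrared fingerprinting and plant-available phosphorus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf infrared fingerprinting and plant-available phosphorus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phospec)
```

## The problem

Plant-available phosphorus (P) in the root zone of a perennial grass is very
hard to measure directly: chemical soil extractions (Bray, Olsen, Mehlich
III) capture only a fraction of one inorganic pool, while deep, adaptive
root systems and rhizosphere microbiota change what is actually available
over a season. Leaf tissue, on the other hand, integrates what the plant
really experienced. `phospec` implements a leaf-spectra-to-phosphorus
pipeline built on that idea: mid-infrared (ATR-FTIR) absorbance spectra of
ground leaf tissue are deconvolved into biochemical band signatures, and a
regression trained on plants grown at known medium P predicts the
plant-available P concentration for new leaves.

Two phosphorus signatures are central. The phosphoryl P=O stretch near
1200 cm^-1 tracks inorganic phosphate (Pi); the P–O–H / P–O–C deformation
near 980 cm^-1 tracks organic phosphates (Po). Both sit on the broad
polysaccharide C–O–C absorption around 1000 cm^-1, which is why the package
always fits them jointly with that broad band rather than in isolation.
Cellulose (C–O–C ether, ~1160 cm^-1) and lignin (aromatic C=C,
~1510 cm^-1) give the cellulose/lignin (C/L) ratio, a feedstock-quality
metric that responds strongly to P limitation; amide II (~1550 cm^-1) and
the lipid carbonyl (~1710 cm^-1) complete the profile.

## The forward model (synthetic data)

No raw spectra ship with the package; a forward model generates datasets
with the statistical structure the analysis assumes, with known ground
truth, so every stage is testable.

**Design.** The lab scenario reproduces a sand-culture dose-response
design: five P levels (1, 10, 30, 150, 500 µM at optimal 6 mM N) and five N
levels (0.01, 0.1, 0.3, 1.5, 6 mM at optimal 500 µM P). The optimal
condition is shared, giving 9 unique conditions with 9 replicate plants
each; three plants at 1 µM P die before harvest, leaving 78 plants, each
measured as triplicate technical spectra (234 spectra).

**Dose-response curves.** Latent band amplitudes are piecewise-smooth
saturating functions of log10 concentration: cellulose rises with P with a
logistic threshold centered between 30 and 150 µM; lignin declines
gradually and linearly in log P; lipid and amide are elevated under severe
P starvation; Pi and Po increase with P; amide and lipid also increase with
N. The cellulose low-P plateau is calibrated at run time (one-dimensional
root finding) so that the cellulose/lignin amplitude ratio at 500 µM P is
*exactly* 3 times its mean over the 1–30 µM conditions — the headline
contrast the downstream quantification is expected to recover.

```{r dose}
dose_response(c(1, 30, 500), 6)
```

**Spectra.** A spectrum is a sum of Gaussian oscillators (centers and widths
in `generator_bands()`), a gentle random convex quadratic baseline, and
i.i.d. Gaussian noise, on a 600–4000 cm^-1 grid at 2 cm^-1 spacing
(1701 points, consistent with 4 cm^-1 instrument resolution). Gaussian
lineshapes are the default because condensed-phase ATR bands are
inhomogeneously broadened and the area has a closed form
(`amplitude * sigma * sqrt(2*pi)`); a Lorentzian alternative is available.

**Noise defaults.** The study's replicate dispersions are not published as
a noise model, so the defaults are the package's own choice, made once:
plant-level biological variation is an independent lognormal factor per
band (sd 0.05 on the log scale for the lab, reflecting a controlled sand
culture with homogenized freeze-dried tissue; 0.12 for the field), and
additive spectral noise has sd 0.003 absorbance units. All are arguments.

**Field scenario.** Two sites with contrasting available P × 30 plants × 5
timepoints (T1 early vegetative … T5 senescence), one spectrum per
plant-timepoint. Latent available P rises to T4 and drops at senescence.
On top of the dose-response, seasonal modifiers encode: leaf Pi rising
through the season with a T5 spike at the high-P site; Po plateauing near
T4 and declining at T5 at the high-P site; a declining C/L ratio as plants
mature. Each plant's second-year biomass is a linear function of its T5
Pi/Po amplitude ratio plus Gaussian noise, so the senescence-remobilization
association is positive by construction. A single `site_effect` parameter
scales every between-site difference; at 0 the sites are exchangeable,
which is how the null behaviour of the statistics module is tested.

What the generator deliberately does *not* emulate: atmospheric CO2/water
vapor lines, ATR penetration-depth dispersion, scatter effects, detector
drift, soil chemistry. Passing tests therefore show the pipeline recovers
truth under the stated noise model, not that it is robust to every
instrumental artifact of real field data.

## Preprocessing

The order is fixed and recorded in a provenance attribute: restrict to the
modeling region [800, 1800) cm^-1, baseline-correct each technical
spectrum, average replicates per plant, then (optionally) normalize.
Normalization and averaging do not commute unless replicates share a
maximum, so the order is part of the contract.

Three baseline estimators are provided: rubber-band (lower convex hull,
parameter-free, the default), asymmetric least squares (Eilers-style,
smoothness `lambda` = 1e5, asymmetry `p` = 0.001), and an iterative
modified-polynomial fit (degree 3). All regions use the half-open
convention [lo, hi) so adjacent windows tile without double counting.

Two normalization scopes are implemented (per-spectrum maximum over the
modeling region, or globally); which scope the original analysis used is
not stated anywhere, so neither is asserted. The *model path* (see below)
uses no normalization at all, because the regression is defined on
baseline-corrected absorbance and Beer-law scale is informative;
max-normalization is a presentation device for comparing relative band
responses, and band ratios such as C/L and Pi/Po are invariant to it
either way.

## Band quantification

Each congested window — [900, 1300) with four oscillators (Po, broad
polysaccharide, cellulose, Pi), [1450, 1620) with two (lignin, amide II),
[1650, 1780) with one (lipid) — is fitted by bounded Levenberg–Marquardt
least squares (via minpack.lm). Initialization: centers at the assignment
defaults, widths at the assignment's `sigma_init`, amplitudes from the
local signal height; centers are bounded within ±15 cm^-1 of their
assignment (also the band-matching tolerance), widths within per-band
bounds (the broad polysaccharide band may be 30–120 cm^-1 wide, sharp
bands 3–30 cm^-1), amplitudes nonnegative.

`quantify_profile()` adds a free *local linear baseline* term per window.
The rationale is a small but systematic effect: a rubber-band hull on a
noisy spectrum follows the lower envelope of the noise, leaving a positive
offset of roughly two noise standard deviations under the bands. Without
the local term that offset inflates small bands (lignin at high P) more
than large ones and biased the recovered C/L fold-change low by ~3%; with
it, the noiseless and noisy diagnostics agree with the generator truth to
better than 1%. `fit_oscillators()` keeps the term off by default so that
exact-recovery oracle tests address the pure oscillator model.

Concentrations are band areas times Beer coefficients. The coefficients
default to 1 — the package reports *relative* concentrations, matching the
normalized-absorbance presentation of the underlying study; hooks for
absolute calibration exist but ship uncalibrated. Consequence: the
quantified C/L ratio is the amplitude ratio times the fitted width ratio
(~10/9 under generator defaults); this constant cancels in every
between-condition contrast, which is why fold-changes are the quantity
compared against truth. `cl_ratio` is reported as `NA` when the lignin
concentration falls below 1e-6.

## The regression

`fit_pcr()` is a plain principal-component regression: center the spectra
matrix, take the leading right singular directions as loadings (for tall
matrices via the eigendecomposition of the cross-product, with a
largest-element-positive sign convention so results are invariant to row
order), and regress log10 concentration on the scores by ordinary least
squares. log10 is the default target scale because the design spans 1–500
µM (2.7 decades); identity is available. Centering only, no unit-variance
scaling — the conventional PCR choice for spectra, where amplitude carries
the signal.

`bootstrap_train()` draws 6000 plant-level resamples with replacement from
the 78 plants to build the training matrix, selects the component count by
10-fold cross-validation, and fits the final model at the selected count.
Two statistical details matter:

* **Fold assignment keeps plants whole.** All bootstrap copies of one
  plant land in the same fold. Assigning rows independently would place
  duplicates of a training plant in the test fold and deflate the MSEP
  estimate several-fold; the grouped assignment makes the reported MSEP an
  honest estimate of error on unseen plants.
* **Tie-breaking.** The smallest component count achieving the minimal
  MSEP is selected. On the default synthetic lab data the CV chooses ~4–8
  components out of the 41 allowed: the synthetic spectra have exactly
  seven latent bands, so this is the expected order of magnitude, and the
  41-component cap is honored as configuration rather than forced.

`predict_available()` refuses a grid that differs from the training grid —
resampling is available but always explicit (`resample_to_grid()`), never
silent.

Typical numbers on the default seeded synthetic lab set (78 plants,
triplicates averaged, baseline-corrected): cross-validated MSEP at the
selected component count ≈ 0.006–0.010 (log10 µM)^2, i.e. ~0.09 log units
RMSEP, and held-out R^2 ≈ 0.99 on the log scale. These are properties of
the synthetic noise model as much as of the estimator; the suite asserts
MSEP ≤ 0.01 and held-out R^2 ≥ 0.95.

## Seasonal statistics

`compare_groups()` wraps the two-sided two-sample t-test. Welch is the
default — the two field sites have unequal variances by design — with the
classical pooled-variance variant selectable. `pairwise_timepoints()`
compares consecutive timepoints (T1–T2 … T4–T5) within a site and adjusts
with Holm across the family; no adjustment scheme is claimed to be the
original one, the consecutive-pair family is a documented convention.
`ratio_biomass_association()` uses Spearman rank correlation, chosen
because only an "association" is claimed and ranks are robust to the
unknown functional form. Timepoints with fewer than two plants are skipped
with a logged message.

## Numerical choices, degenerate inputs, limitations

* Half-open [lo, hi) intervals everywhere; grids stored strictly
  ascending; descending input is re-ordered, non-monotone input rejected.
* Rank decisions use a relative threshold of 1e-8 on singular values;
  requesting more components than the rank is a typed error, and the CV
  caps the candidate count at the smallest training-fold rank with a
  warning.
* The oscillator solver runs with tight tolerances (ftol = ptol = 1e-14,
  300 iterations); `converged` is reported per window and the residual
  trace is exposed so the non-increase of the objective is checkable.
* Zero spectra fit to zero amplitudes; constant samples are rejected by
  the t-test and correlation with typed errors; a nonpositive maximum is a
  normalization error, not a silent NaN.
* Seeds: every stochastic operation takes one; identical seeds give
  bit-identical output. The pipeline derives per-stage seeds from one
  top-level seed as `(seed mod 1e6) * 1000 + stage offset`.
* Problem sizes: the default experiment is deliberately desk-scale — 234
  lab spectra of 1701 points, restricted to 500 points for modeling, 6000
  bootstrap rows — and the full train-and-report cycle runs in seconds on
  one CPU.

Known limitations: no Voigt lineshape (Gaussian/Lorentzian only); no
atmospheric compensation or scatter correction (MSC/SNV); Beer
coefficients uncalibrated, so concentrations are relative; the field
statistics mirror the generator's design and have not been exercised
against vendor-format field data (OPUS/SPC readers are out of scope).
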