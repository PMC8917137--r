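# phospec

Leaf mid-infrared band deconvolution and plant-available phosphorus
regression.

## The problem

Phosphorus availability in the root zone of a perennial grass such as
switchgrass cannot be read off a soil extraction: chemical extracts (Bray,
Olsen, Mehlich III) sample one inorganic pool near the surface, while deep
adaptive roots and their microbiome change what is actually
plant-available over a season. Leaf tissue integrates what the plant
really experienced. `phospec` is for plant scientists and feedstock
researchers who want to use the leaf itself as the sensor: ATR-FTIR
absorbance spectra of ground leaf tissue are deconvolved into biochemical
band signatures, and a regression trained on plants grown at known medium
P predicts the plant-available P concentration for new leaves.

## The method

A leaf spectrum `A(nu)` on a 600–4000 cm⁻¹ grid is modelled, window by
window, as a sum of Gaussian oscillators

    A(nu) = sum_i a_i exp( -(nu - c_i)^2 / (2 s_i^2) ) + baseline,

fitted by bounded Levenberg–Marquardt least squares. Band assignments:
inorganic phosphate (P=O stretch, ~1200 cm⁻¹), organic phosphate
(P–O–H/P–O–C deformation, ~980 cm⁻¹) — both fitted jointly with the broad
polysaccharide C–O–C absorption near 1000 cm⁻¹ on which they sit —
cellulose (~1160), lignin (~1510), amide II (~1550), lipid carbonyl
(~1710). By Beer's law the closed-form band area `a_i s_i sqrt(2*pi)` is
proportional to the concentration of the absorbing species; the
cellulose/lignin (C/L) ratio is the feedstock-quality readout.

Prediction of medium P uses principal-component regression: spectra are
baseline-corrected (rubber-band / ALS / polynomial), technical replicates
averaged, the matrix centered, and `log10(P)` regressed on the leading
principal-component scores. Training augments the 78-plant dose-response
design with 6000 plant-level bootstrap resamples; the component count is
chosen by 10-fold cross-validation (MSEP, folds grouped by source plant so
bootstrap copies never leak across the split).

A forward model (`simulate_lab_dataset()`, `simulate_field_dataset()`)
generates the sand-culture dose-response design (5 P levels × 5 N levels
sharing the optimal condition, 9 replicates, 3 deaths at 1 µM P, 78
plants, triplicate spectra) and a two-site × 30-plant × 5-timepoint field
season with known ground truth, so the whole pipeline is testable without
any data download. See `vignettes/phospec-methods.Rmd` for the models,
assumptions and numerical choices.

## Worked example

```r
library(phospec)

lab <- simulate_lab_dataset(seed = 1)
lab$spectra
#> <spectrum_set> 234 spectra, 1701 points, 600-4000 cm^-1
#> metadata columns: sample_id, plant_id, series, p_conc, n_conc, condition, replicate

pp <- preprocess_set(lab$spectra, preprocess_config(normalization = "none"))
targets <- setNames(lab$truth$p_conc, lab$truth$plant_id)
trained <- bootstrap_train(pp$set, targets, n_resamples = 6000,
                           folds = 10, max_components = 41, seed = 1001)
trained$cv
#> <cv_result> 10-fold CV over 41 component counts: selected 4 (MSEP 0.007102)
trained$model
#> <pcr_model> 4 components, 500-point spectra, log10 target, train RMSE 0.07496
```

The cross-validated MSEP of 0.0071 (log10 µM)² — about 0.08 log units of
prediction error on unseen plants — meets the MSEP < 0.01 selection
criterion. Predictions come back on the µM scale:

```r
pred <- predict_available(trained$model, pp$set)
head(cbind(pred[1:2], true_uM = targets[pp$set$metadata$plant_id]), 4)
#>          sample_id predicted true_uM
#> plant001  plant001      1.08       1
#> plant002  plant002      1.35       1
#> plant003  plant003      1.42       1
#> plant004  plant004      0.98       1

quantify_profile(pp$set["plant075"])[, c("sample_id", "Pi", "Po",
                                         "cellulose", "lignin", "cl_ratio")]
#>   sample_id   Pi  Po cellulose lignin cl_ratio
#> 1  plant075 7.33 7.2        20   6.68     2.99
```

Plant 75 grew at the optimal condition (500 µM P): high cellulose, low
lignin, C/L ratio near 3 — the P-replete phenotype. `run_lab_training()` /
`run_field_analysis()` orchestrate the full simulate → preprocess → train
→ quantify → predict → report cycle with YAML config and logged
provenance, and `inst/scripts/phospec-cli.R` wraps them as shell
subcommands.

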