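Package: phospec
Title: Leaf Mid-Infrared Band Deconvolution and Plant-Available Phosphorus Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for metabolic fingerprinting of plant leaf tissue from
    attenuated-total-reflection Fourier-transform infrared (ATR-FTIR)
    absorbance spectra. Provides a forward simulator for nutrient-limitation
    experiments, readers and writers for wide-table and JCAMP-DX-like
    spectrum files, baseline correction and normalization, oscillator-model
    least-squares deconvolution of biochemical bands (inorganic and organic
    phosphate, cellulose, lignin, amide, lipid) with Beer-law quantification
    and the cellulose-to-lignin ratio, a bootstrap-augmented
    principal-component regression with 10-fold cross-validated component
    selection that predicts plant-available phosphorus in the growth medium
    from leaf spectra, and seasonal group-comparison summaries for field
    campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
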