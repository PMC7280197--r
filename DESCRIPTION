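Package: verdictmri
Title: Three-Compartment VERDICT Modelling of Brain-Tumour Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microstructural modelling of brain-tumour diffusion MRI
    with the three-compartment VERDICT (Vascular, Extracellular and Restricted
    Diffusion for Cytometry in Tumours) ball/sphere/stick model. Provides
    pulsed-gradient spin-echo (PGSE) acquisition-scheme construction and I/O
    with Stejskal-Tanner b-value computation, TE-matched b0 normalisation of
    diffusion-weighted volumes, Gaussian-phase-distribution restricted-sphere
    signals, voxel-wise constrained maximum-likelihood fitting under Rician
    noise with multi-start optimisation, BIC comparison against ADC and
    diffusion-kurtosis models, longitudinal two-arm treatment-response
    statistics (Holm-Sidak corrected group comparisons, consecutive-timepoint
    effect sizes, Spearman correlation, repeatability coefficients), k-means
    estimation of stained-tissue fraction from histology images, and fully
    synthetic phantom, cohort and histology generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
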