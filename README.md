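# verdictmri

Three-compartment microstructural modelling of brain-tumour diffusion MRI
in R, for imaging scientists who want cell-scale biomarkers — sphere
radius and compartment volume fractions — from multi-shell pulsed-gradient
spin-echo (PGSE) data, rather than summary diffusivities alone.

## What it computes

The VERDICT (Vascular, Extracellular and Restricted Diffusion for
Cytometry in Tumours) ball/sphere/stick model writes the b0-normalised
voxel signal as a fraction-weighted sum of three water pools,

> S = f_ball·S_ball + f_sphere·S_sphere + f_stick·S_stick,

with S_ball = exp(−b·d_ball) (isotropic extracellular diffusion),
S_stick = exp(−b·d_stick·(g·n)²) (one-dimensional vascular
pseudodiffusion along n(θ, φ)) and S_sphere the Gaussian-phase-distribution
signal of water restricted in impermeable spheres of radius R — the
cell-size-sensitive compartment. Fractions are constrained to sum to one
(f_stick by closure), R to 0.1–20 µm, and fitting maximises the Rician
log-likelihood voxel-by-voxel with multi-start Nelder-Mead in a
transformed, bound-free space. ADC (S = exp(−b·ADC)) and diffusion-kurtosis
(S = exp(−b·D_k + b²·D_k²·K/6)) fits and per-voxel BIC model comparison
are included, as are the longitudinal two-arm statistics used for
treatment-response studies (Holm–Šidák-corrected t-tests,
consecutive-timepoint effect sizes, Spearman ρ, repeatability
coefficients), k-means stained-fraction estimation from histology images,
and seed-deterministic synthetic generators (tumour phantom, longitudinal
cohort, histology image) so the whole pipeline is testable without any
acquired data.

## Worked example

Fit one tumour voxel acquired with the 46-combination preclinical
protocol, simulated at SNR 50 from the pre-therapy tumour parameters
(f_sphere 0.54, f_ball 0.39, R 10.6 µm, d_stick 10.8e-9 m²/s):

```r
library(verdictmri)

scheme <- buildMouseProtocol()
scheme
#> AcquisitionScheme with 184 measurements
#>    138 diffusion-weighted, 46 b0; 46 unique (delta, Delta, G) combinations
#>   b range: 8 - 3779 s/mm^2
#>   TE range: 23 - 60 ms

truth <- list(fBall = 0.39, fSphere = 0.54, fStick = 0.07,
              dBall = 2e-9, dSphere = 1e-9, R = 10.6,
              dStick = 10.8e-9, theta = 1, phi = 0.5)
signal <- verdictSignal(scheme, truth)[!isB0(scheme)]
noisy  <- addRicianNoise(signal, 1/50, seed = 42)

fit <- fitVoxel(noisy, scheme, fitConfig("verdict", "mouse",
                                         sigma = 1/50, seed = 1))
fit
#> VoxelFit: 138 measurements, k = 6
#>   logLik = 342.591  BIC = -655.619
#>    fSphere = 0.5541, fBall = 0.3664, fStick = 0.07956, R = 10.78,
#>    dStick = 1.403e-08, theta = 1.057, phi = 0.4823
```

The fit recovers the sphere fraction within 0.015 and the radius within
0.2 µm of the generating values at this noise level; `fStick` is the
closure `1 - (fSphere + fBall)`, never a fitted parameter, and `bic` is
`ln(138)·6 − 2·logLik`.

Simulate a 12-per-arm longitudinal cohort (control growth vs
chemotherapy-induced radius shrinkage) and ask at which day the radius
separates the arms after familywise correction over 32 comparisons:

```r
coh <- generateCohort(cohortSpec(nPerArm = 12, seed = 7))
gc  <- groupComparison(coh$table, familySize = 32)
subset(gc, parameter == "R")
#>    parameter day      t df        p pAdjusted significant
#> 25         R   0 -0.134 22 8.95e-01  1.00e+00       FALSE
#> 26         R   3 10.393 22 5.96e-10  1.49e-08        TRUE
#> 27         R   6 15.304 22 3.28e-13  9.51e-12        TRUE
#> 28         R   9 22.585 22 1.04e-16  3.55e-15        TRUE
```

The radius is indistinguishable at baseline (randomised arms) and
significant from day 3 onward — the earliest-response behaviour the model
is designed to capture.

`runPipeline(config)` sequences phantom simulation, TE-matched b0
normalisation, voxel-wise fitting of all three models, BIC comparison and
the cohort statistics into one seeded, manifest-logged run; see the
methods vignette (`vignettes/verdict-methods.Rmd`) for the model details
and every numerical choice.

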