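# stenoshape

Geometry-aware, data-driven lumped (0D) arterial stenosis modeling in R.

Lumped stenosis elements used inside 1D pulse-wave network models usually
assume idealized (cosinusoidal or trapezoidal) lesion shapes, or use only the
minimal and reference radii. Real coronary lesions are irregular, and those
simplifications propagate into trans-lesional pressure-drop and fractional
flow reserve (FFR) errors. `stenoshape` implements an alternative: describe
each lesion by a handful of statistical shape coefficients and *learn* the
lumped model's loss coefficients from reference pressure-drop data.

The lumped pressure-drop law is

    dp = Kv * h1(q) + Kt * h2(q^2)
    h1(q)   = 8 mu ls q / (pi a0^4)          (viscous, linear in flow)
    h2(q^2) = rho/2 * (q / (pi a0^2))^2      (expansion, quadratic in flow)

with `q` the volumetric flow, `mu` viscosity, `rho` density, `ls` the lesion
length, `a0` the healthy reference radius, and `Kv`, `Kt` geometry-dependent
loss coefficients. The package provides the full pipeline:

1. **geometry synthesis** — cohorts of axisymmetric stenotic vessels on 20
   cross-sectional planes (1 mm apart): Sobol-sampled severities on
   [0.3, 0.8], random lesion boundary/center planes, a Gaussian radius taper
   with width sigma ~ U(1, 3) and ±10% per-plane noise, plus a 30 mm
   cylindrical CFD outflow extension and surface lofting;
2. **statistical shape model** — PCA of template-to-target per-vertex
   displacement fields on the shared vertex grid; each geometry is encoded
   by its coefficient vector alpha;
3. **flow oracle** — a desk-scale reference data generator standing in for a
   3D CFD campaign: 13 Reynolds numbers from 0.1 to 500 per geometry,
   Poiseuille baseline subtraction, and a 60 mmHg physiological exclusion
   cap;
4. **loss-coefficient fitting** — the two-regime through-origin
   least-squares procedure (Kv from Re < 10, Kt from the residual at
   Re >= 10);
5. **coefficient regression** — two exact Gaussian-process regressors
   (composite RBF/Matérn + white kernel, optional polynomial enrichment and
   log-target transform) mapping alpha to Kv and Kt, tuned by a
   TPE-style 20-trial search with 5-fold cross validation;
6. **0D stenosis element** — pressure-drop and FFR prediction from
   (alpha, q), the resistance/under-relaxation coupling law for embedding in
   a pulse-wave network, and the classical geometry-based comparator model;
7. **evaluation** — identity-line R², RMSE/σ calibration, Bland–Altman,
   FFR agreement and threshold classification, ROC AUC with the DeLong test.

## Worked example

```r
library(stenoshape)

cfg <- pipeline_config(n = 100, n_trials = 10, k_folds = 5,
                       out_dir = "run100")
run <- run_full_pipeline(cfg)
s <- attr(run, "summary")
round(unlist(s$metrics$kv), 3)
#>                    r2                  rmse mean_predictive_sigma
#>                 0.805                 9.928                 2.015
#>      rmse_sigma_ratio                     n
#>                 4.928                10.000

round(unlist(s$metrics$ffr), 3)
#> within_0p02    accuracy        bias     loa_low    loa_high
#>       0.832       0.982       0.010      -0.055       0.074
```

`r2` is the coefficient of determination about the identity line between
predicted and fitted Kv on the 10 held-out geometries; `rmse_sigma_ratio`
compares prediction error with the GP's own uncertainty (1 = well
calibrated, larger = overconfident). The FFR block reports the fraction of
held-out flow samples whose predicted FFR lies within 0.02 of the reference,
classification accuracy at the 0.80 ischemia threshold, and Bland–Altman
bias/limits. A human-readable rendering is produced by
`export_report(run)`, and a thin CLI over the same functions is installed at
`inst/cli/stenoshape.R`.

Predicting for one geometry:

```r
objs <- attr(run, "objects")
alpha <- as.numeric(objs$table[objs$table$id == "geom_0007",
                               paste0("alpha_", 1:5)])
str(predict_dp(objs$bundle, alpha, q = 3.33e-6))
#> List of 6
#>  $ dp      : num 2827     # Pa, ~21 mmHg at the hyperemic reference flow
#>  $ dp_sigma: num 382
#>  $ kv      : num 7.08
#>  $ kt      : num 20.5
#>  $ kv_sigma: num 0.209
#>  $ kt_sigma: num 3.24
```

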