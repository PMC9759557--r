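# polarleaf

Stokes polarimetric imaging analysis for plant stress phenotyping.

Transmission polarimetry is a non-contact way to watch a living leaf grow:
as a seedling lays down aligned cell-wall material and chiral solutes, the
leaf's linear and circular retardance rise, and so does the circular
polarization component of light transmitted through it. `polarleaf`
implements the full analysis chain for a single-rotating-retarder Stokes
imaging polarimeter (fixed 135° input polarizer → leaf → rotating
quarter-wave plate → analyzer → camera), aimed at plant scientists and
biophotonics groups who want to quantify growth and salt stress from
polarization images.

## What it computes

For the plate at angle θ = ωt + φ₀, each pixel's intensity follows

    I(t) = ½ [ A − B sin 2θ + C cos 4θ + D sin 4θ ]

and the harmonic coefficients give the Stokes parameters of the light
leaving the leaf:

    S0 = A − C,  S1 = 2C,  S2 = 2D,  S3 = B.

The package

* fits the harmonics per pixel by linear least squares
  (`fit_fourier_stack()`), exact on noiseless data and tolerant of
  non-uniform timestamps;
* masks pixels with abnormal degree of polarization (strictly outside
  0 < DOP < 1, plus a dim-pixel floor) and normalizes to S0 = 1
  (`dop_mask()`, `normalize_stokes()`);
* characterises the circular component |s3| with median/MAD summaries and a
  maximum-likelihood **generalized extreme value** (GEV) fit
  (ξ, μ, σ) per replicate image (`gev_fit_mle()`, `characterize_s3()`);
* relates the GEV parameters to growth time and NaCl concentration: ANOVA
  day-trends of ξ, Spearman correlations, per-day OLS of μ on concentration
  with 95% confidence bands, and a salt-stress flagging rule based on
  one-sided Wilcoxon tests (`gev_trend_anova()`,
  `spearman_param_vs_concentration()`,
  `regress_location_vs_concentration()`, `classify_salt_stress()`);
* visual summaries of the polarization state as a density on the Poincaré
  sphere (`poincare_density()`);
* Lu–Chipman polar decomposition of measured 4×4 Mueller matrices into
  diattenuation (D, LD, CD), retardance (R, LR, CR) and depolarization
  (`lu_chipman()`);
* a **synthetic leaf simulator** (`leaf_model()`, `growth_model()`,
  `build_leaf()`, `simulate_acquisition()`, `simulate_study()`): per-pixel
  retarder/diattenuator/depolarizer Mueller fields whose retardance grows
  with time and is suppressed by salt, imaged through the full optical train
  with detector noise. It generates the default 5 concentrations × 6 days ×
  5 replicates study and makes every stage testable end to end.

Interchange formats: multi-page float TIFF + JSON sidecar for image stacks,
4×4 CSV for Mueller matrices, CSV fit tables, YAML/JSON pipeline configs
(`run_pipeline()`, `read_pipeline_config()`).

## Worked example

```r
library(polarleaf)

leaf  <- leaf_model()                 # 128x128 px, beam radius 48 px
grow  <- growth_model()               # delta0 = 0.15 rad, g = 0.035 rad/day
field <- build_leaf(leaf, grow, day = 10, conc = 0, seed = 1)
stack <- simulate_acquisition(field, frames = 64, seed = 2)
stack
#> Intensity stack: 64 frames of 128 x 128 px, t = 0 .. 0.3093 s

img <- reconstruct_stokes(stack)
img
#> Stokes image 128 x 128 px; 7232 valid px (44.1%) ; normalized (S0 = 1)

fit <- gev_fit_mle(abs_s3_samples(img))
fit
#> GEV MLE (n = 7232): xi = 0.5470, mu = 0.04204, sigma = 0.04235, logLik = 9244.82
```

The 44% valid fraction is the circular beam inside the square frame: the
DOP filter removes the dark background and dim beam-edge pixels (mean
valid-pixel DOP here is ≈ 0.75). After ten days of unstressed growth the
fitted GEV location μ ≈ 0.042 — up from ≈ 0.018 at day 0 — because the
accumulated leaf retardance converts more of the 135°-linear input into
circular polarization.

Salt stress suppresses exactly that rise. A small study (3 days × 5
concentrations × 3 replicates) shows the day-10 dose response:

```r
cfg <- pipeline_config(design = study_design(days = c(0, 4, 10),
                                             replicates = 3, seed = 1),
                       seed = 1)
ft  <- run_study(cfg)                 # one GEV fit per (conc, day, replicate)
r10 <- regress_location_vs_concentration(ft, day = 10)
#> day-10 slope: -5.51e-05 per mM (95% CI -6.21e-05 .. -4.8e-05)
s10 <- spearman_param_vs_concentration(ft, "mu", day = 10)
#> day-10 Spearman rho(mu, NaCl) = -0.982, p = 8.6e-11
```

A negative slope with a confidence interval excluding zero — the fitted
location falls by about 5×10⁻⁵ per mM of NaCl — while the same regression
at day 0 straddles zero: before treatment there is nothing to detect.

See `vignettes/polarleaf-methods.Rmd` for the measurement model, the
simulator's assumptions, and every tunable parameter.

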