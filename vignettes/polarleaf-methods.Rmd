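---
title: "Methods: rotating-retarder Stokes polarimetry and GEV analysis of leaf circular polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rotating-retarder Stokes polarimetry and GEV analysis of leaf circular polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarleaf)
```

## The measurement model

`polarleaf` analyses transmission polarimetry of plant leaves with a
single-rotating-retarder Stokes polarimeter. The optical train is: an
unpolarized source, a fixed linear polarizer at 135°, the leaf, a
quarter-wave plate (retardance $\delta = \pi/2$) rotating at constant angular
speed $\omega$ (20 rad/s by default), and a horizontal analyzer
($\alpha = 0$) in front of the camera. Writing
$\theta = \omega t + \varphi_0$ for the plate's fast-axis angle, the detected
intensity at one pixel is the classic four-harmonic modulation

$$I(t) = \tfrac{1}{2}\left[A - B\sin 2\theta + C\cos 4\theta + D\sin 4\theta\right],$$

whose coefficients carry the Stokes vector of the light leaving the leaf:

$$S_0 = A - C,\qquad S_1 = 2C,\qquad S_2 = 2D,\qquad S_3 = B.$$

The sign of the $\sin 2\theta$ term fixes a handedness convention; the
retarder Mueller matrix implemented in `retarder_mueller()` is chosen so that
the explicit chain `analyzer %*% retarder %*% S` reproduces exactly this
expansion, and a dedicated convention test asserts the agreement (closed form
versus matrix chain to $10^{-10}$ over random physical states). All angles
are radians internally; configuration files may use `*_deg` keys.

### Reconstruction

`fit_fourier_stack()` estimates $(A, B, C, D)$ per pixel by linear least
squares on the design matrix
$\tfrac12[1, -\sin 2\theta_t, \cos 4\theta_t, \sin 4\theta_t]$ rather than by
FFT. For uniform full-rotation sampling the two are equivalent and the fit is
exact on noiseless data; the least-squares form additionally tolerates
non-uniform timestamps and reports a per-pixel residual RMS. Four frames are
the hard minimum (the design has four columns); fewer than a full rotation of
coverage triggers a warning because the harmonics become poorly conditioned.
If the initial plate phase $\varphi_0$ is missing from acquisition metadata,
`estimate_phi0()` recovers it (modulo $\pi/2$, the symmetry of the
$4\theta$ harmonic) from a no-sample reference acquisition.

### Pixel quality control

The degree of polarization $\mathrm{DOP} =
\sqrt{S_1^2 + S_2^2 + S_3^2}/S_0$ is the main QC signal. `dop_mask()` keeps
pixels with $0 < \mathrm{DOP} < 1$ — strict inequalities, so exactly
unpolarized and unphysical ($\ge 1$) estimates are both excluded — and, by
default, applies an intensity floor of 5% of the median positive $S_0$.
The floor encodes the empirical observation that abnormal DOP values come
almost entirely from dim pixels at the beam edge, where read noise dominates
the harmonic fit. Surviving pixels are normalized to $S_0 = 1$
(`normalize_stokes()`), giving the lowercase components $(s_1, s_2, s_3)$;
invalid pixels become `NA`.

## GEV characterisation of $|s_3|$

The circular component $s_3$ of leaf-transmitted light is distributed
two-sidedly around zero; its absolute value $|s_3|$ has a single right-skewed
distribution that is well described by the generalized extreme value family

$$f(s;\xi) = (1+\xi s)^{-(1+1/\xi)}\exp\left[-(1+\xi s)^{-1/\xi}\right],
\qquad s = \frac{x - \mu}{\sigma},$$

on its support $1 + \xi s > 0$ and zero elsewhere, with the Gumbel density
$\exp(-s)\exp[-\exp(-s)]$ as the $\xi \to 0$ limit. `gev_fit_mle()` maximizes
the log likelihood with Nelder–Mead over $(\mu, \log\sigma, \xi)$, starting
from Hosking's probability-weighted-moments estimates, with the support
constraint enforced by a penalty; fits report convergence, log likelihood and
(optionally) Hessian-based standard errors. The fit is deterministic for a
given sample. Robust summaries (`summary_median_mad()`) use the raw,
unscaled median absolute deviation — no 1.4826 consistency factor — since the
quantity reported alongside the medians is literally the median absolute
deviation.

GEV parameters are fitted **per replicate image** and then averaged or
compared across replicates, not pooled across replicates before fitting:
replicate leaves are distinct plants, and pooling would mix distributions
with different locations and inflate the fitted scale.

Group comparisons use Wilcoxon rank tests (`compare_distributions()`). The
default is the two-sample rank-sum variant because pixel samples from
different plants have no natural pairing and unequal valid-pixel counts; the
paired signed-rank variant is available for genuinely paired designs and
returns $p = 1$ by convention when every paired difference is zero.
`poincare_density()` bins unit Poincaré directions on an equiangular
72 × 36 (azimuth × latitude) grid with per-bin solid-angle weights, so the
reported density (per steradian) integrates to one regardless of binning.

## Trend inference

With one fitted row per (concentration, day, replicate):

* `gev_trend_anova()` — one-way ANOVA of a parameter (typically $\xi$)
  across days at one concentration, with significance stars
  `***`/`**`/`*` for $p < 0.001 / 0.01 / 0.05$.
* `spearman_param_vs_concentration()` — rank correlation of a parameter
  with concentration at one day, on replicate-level pairs.
* `regress_location_vs_concentration()` — OLS of $\mu$ on concentration at
  one day with 95% t-based confidence intervals and a confidence band.
  $\mu$ is the default regressand; `response = "median"` switches to the
  robust median of $|s_3|$. Replicate-level rows enter the regression (for a
  balanced design the slope is identical to regressing replicate means).
* `classify_salt_stress()` — a group is flagged stressed when its $|s_3|$
  sample is significantly *below* the untreated reference (one-sided
  rank test) and its median is below the reference median.

No multiple-testing correction is applied across days or parameters by
default, mirroring how such screens are usually reported; the p-values are
returned so callers can apply `p.adjust()` if desired.

## The synthetic leaf generator

Raw imaging data for this kind of experiment are rarely published, so the
package ships a Mueller-optics simulator that stands in for them and makes
every pipeline stage testable end to end. Each in-beam pixel receives

$$M = M_{\text{depol}} \cdot M_{\text{circ}}(\mathrm{CR}) \cdot
      M_{\text{lin}}(\delta_{\text{pix}}, \theta_{\text{pix}}) \cdot
      M_{\text{diat}}(d, \theta_{\text{pix}}),$$

with per-pixel draws that are deterministic given the seed:

* **Linear retardance** $\delta_{\text{pix}} \sim$ Gamma(shape $k = 4$,
  mean $\bar\delta(t, c)$ scaled per region). The Gamma law produces the
  right-skewed, extreme-value-like $|s_3|$ distributions observed in real
  leaves; shape 4 gives a coefficient of variation of 0.5, enough dispersion
  for a clearly non-Gaussian tail without degenerate mass at zero.
* **Growth law** $\bar\delta(t, c) = \delta_0 + g\,t\,e^{-c/c_0}$ with
  $\delta_0 = 0.15$ rad, $g = 0.035$ rad/day, $c_0 = 250$ mM: retardance
  (aligned cell-wall material) accumulates with growth and salt stress slows
  the accumulation smoothly and monotonically. Only the direction of both
  effects is empirically established; the exponential form is the simplest
  smooth monotone choice.
* **Fast axis** von Mises about the region orientation (sampled on the
  doubled angle, since an optic axis is $\pi$-periodic). Region means sit
  near 50–90° with concentrations 40–90, chosen so the geometry factor
  $|\cos 2\theta|$ maps the day-0 mean retardance to $|s_3|$ medians of
  order 0.03 — the magnitude seen in real day-0 leaves.
* **Circular retardance** Normal with mean $0.05\,\bar\delta$ (chiral
  solutes contribute a small optical rotation proportional to overall
  growth).
* **Diattenuation** largest at the midrib (0.12), small in veins (0.04) and
  lamina (0.02), reflecting aligned vascular fibres.
* **Depolarization** diagonal factor 0.75 in all regions, so fully polarized
  input leaves the leaf with DOP 0.75 and the reconstructed mean valid-pixel
  DOP lands near the ~70% observed in practice.
* **Beam** a super-Gaussian transmission profile $e^{-(r/R)^6}$ with
  $R = 48$ px in a 128 × 128 frame; background pixels transmit nothing and
  carry read noise only, so the DOP filter removes them — emulating the
  dim-beam-edge exclusions of real acquisitions.
* **Noise** additive Gaussian with variance $5\times10^{-4} I$ (shot-like)
  plus read noise SD 0.005 on unit-scale intensities.

The default study design is 5 NaCl concentrations (0–400 mM) × 6 days
(0–10) × 5 replicates = 150 acquisitions of 64 frames each (64 frames per
rotation at $\omega = 20$ rad/s comfortably resolves the $2\theta$ and
$4\theta$ harmonics). Per-stack seeds are derived from the master seed by an
integer hash, so replicates differ but reruns are bit-identical.

**What the simulator does not emulate.** It is a phenomenological optical
model, not a biophysical one: no leaf 3-D structure, no wavelength
dependence, no spatial correlation between neighbouring pixels beyond region
membership, and no instrument drift. Passing the end-to-end tests therefore
demonstrates that the *analysis* recovers what the *optics* encode — it does
not validate the biological growth law itself. One visible consequence: the
synthetic $\xi$ (GEV shape) trends with time are much weaker than the
location trends, because the Gamma retardance law moves mostly the location
and scale of $|s_3|$; day-trend ANOVA on $\xi$ is frequently non-significant
on synthetic data even where real data show strong effects.

## Numerical choices

* GEV $\xi = 0$ branch: the Gumbel density; continuity at $\xi \to 0$ is
  tested to $10^{-4}$ on a grid, and values with $|\xi| < 10^{-9}$ are
  routed to the Gumbel branch to avoid catastrophic cancellation.
* The harmonic fit uses one QR factorization shared across pixels; exactness
  on noiseless data is tested at $10^{-12}$.
* Lu–Chipman decomposition (`lu_chipman()`) uses the classic factor order
  $M = M_\Delta M_R M_D$; the depolarizer block is recovered from the
  eigenvalues of $m' m'^T$ with the sign taken from $\det m'$, slightly
  negative eigenvalues (noise) are clipped with a warning above $10^{-3}$,
  an exactly singular diattenuator ($D = 1$) short-circuits to its limit,
  and a near-non-orthogonal retarder block is polar-projected via SVD before
  the retardance extraction. Circular retardance is reported as the
  (signed) rotation of the linear components, i.e. twice the optical
  rotation angle.
* Degenerate inputs fail loudly: constant samples, empty masks, unmasked
  images with non-positive $S_0$, rank-deficient acquisition schedules and
  missing sidecar metadata all raise errors naming the problem.

## Problem sizes used in the shipped tests

Unit tests run on 8–32 px frames and $10^3$–$10^5$-draw Monte-Carlo oracles;
the end-to-end validation runs the full default 150-stack study at
128 × 128 × 64 frames (about a minute on one core) plus $2\times10^5$-sample
GEV refits. These sizes were chosen to keep the Monte-Carlo standard errors
far below the asserted margins (3 SE bounds throughout) while remaining
desk-scale.

## Known limitations

* The GEV location/scale/shape of real leaves depend on instrument
  calibration ($\varphi_0$, plate retardance errors) that the simulator
  idealizes; only $\varphi_0$ estimation is provided.
* `classify_salt_stress()` needs pixel-level samples, not just fitted
  parameters, so classification from a saved fit table alone is not
  possible — rerun the reconstruction with `keep_samples_day` set.
* The rank-sum default for group comparison is a deliberate choice where a
  paired test is not defensible; with tens of thousands of pixels per image
  almost any difference is "significant", so effect sizes (median
  differences) matter more than p-values at pixel scale.
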