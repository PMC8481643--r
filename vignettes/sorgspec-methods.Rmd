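---
title: "Methods: NIR calibration and grading of sorghum grain composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR calibration and grading of sorghum grain composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Sorghum grains are routed to food, feed, or fuel use depending on their
biochemical composition: high tannin (bitter, anti-nutritional) and high
hemicellulose (indigestible, but desirable for biofuel viscosity) push a
grain toward fuel; among low-tannin, low-fiber grains, starch separates
food (≥ 650 g kg⁻¹) from feed. Wet-chemistry assays for the eight relevant
components — starch, protein, fat, tannin, cellulose, hemicellulose,
lignin, ash — are slow and expensive, so the practical route is
Fourier-transform near-infrared (FT-NIR) spectroscopy: absorbance spectra
over 4,000–10,000 cm⁻¹ calibrated against reference chemistry with partial
least squares regression (PLSR).

`sorgspec` implements that calibration workflow end to end, for four
sample presentation formats (whole grains, whole grain flours, hulled
grain flours, hull-less grain flours), together with a seeded synthetic
study generator so that every stage is testable without instrument data.

## The pipeline, stage by stage

For each sample format × analyte cell, `run_pipeline()` executes:

1. **Preprocessing** (`apply_recipe()`): scatter correction (MSC or SNV),
   then Savitzky–Golay (SG) smoothing/derivative, in that order. The
   per-cell defaults ship in `default_recipes()`. Mean-centering is *not*
   part of the recipe: it happens inside model fitting, so recipes are
   stateless apart from the MSC reference spectrum, which is retained so
   validation spectra are corrected against the calibration reference.
2. **Outlier screening** (`screen_outliers()`): two-component PCA of the
   treated spectra; each score column is standardized by its standard
   deviation and samples with T² = z₁² + z₂² above the χ²(2) quantile at
   the 95% level (5.991) are removed *one at a time*, refitting the PCA
   after each removal. A hard floor keeps at least 50% of the samples.
3. **Partitioning** (`split_samples()`): Kennard–Stone (KS) or SPXY with
   calibration size ⌊3n/4⌋ — the 3:1 ratio that reproduces the published
   subset sizes 98 → 73/25, 61 → 45/16, 37 → 27/10. SPXY augments the
   spectral Euclidean distance with the analyte distance, each normalized
   by its maximum; constant y degenerates exactly to KS. Ties break toward
   the lowest sample index, so duplicated spectra never error.
4. **Wavelength selection** (`cars()`): competitive adaptive reweighted
   sampling. Run i of N fits a PLS model on a random 80% of the
   calibration samples, keeps the ⌈r_i·p⌉ variables with the largest
   |regression coefficient| (forced reduction, with
   r_i = (p/2)^(1/(N−1))·e^(−ln(p/2)·i/(N−1)), so r₁ = 1 and r_N = 2/p),
   and then thins the survivors by coefficient-weighted bootstrap
   resampling realized as the unique set drawn. Each run's variable set is
   scored by cross-validated RMSE on the full calibration subset; the
   minimizing run wins. Validation samples never enter CARS.
5. **Model fitting** (`fit_pls()`, `loocv_select()`): NIPALS PLS1 with
   internal mean-centering. The latent-variable count is chosen by
   leave-one-out cross-validation with a parsimony rule: the smallest
   count whose RMSECV is within 2% of the curve minimum.
6. **Evaluation and rating** (`evaluate_model()`, `rate_model()`): R²
   (squared Pearson correlation of predicted vs measured), RMSE, subset
   SDs, RPD = SD/RMSE for cross-validation and validation, and a paired
   t-test of measured vs predicted validation values. Adequacy bands:
   R² > 0.95 & RPD > 4 efficient; 0.9–0.95 & 3–4 successful; 0.8–0.9 &
   2.25–3 satisfactory; 0.7–0.8 & 1.75–2.25 preliminary; else inadequate.
   When R² and RPD disagree, the lower band wins.

Independently of the spectra, `grade_sample()` applies the decision table
(thresholds 15 / 50 / 650 g kg⁻¹, all "equal or more than" boundaries) to
the reference chemistry, and `nrel_composition()` provides the assay
arithmetic (cellulose = 0.9 × glucose, hemicellulose = 0.88 × (xylose +
arabinose), lignin = soluble + insoluble fraction; the 0.88 anhydro factor
is applied to the pentose *sum*, the standard convention — the printed
formula is typographically ambiguous on this point).

```{r example}
library(sorgspec)
study <- simulate_study(study_config(seed = 7))
report <- run_pipeline(study, pipeline_config(seed = 5))
report
autoplot(report)
```

## What the synthetic generator emulates

`simulate_study()` states a world matching the published panel:

* 98 grains — 61 hulled, 37 hull-less — with analyte concentrations drawn
  from truncated normals whose mean/SD/min/max are the published
  per-morphology calibration statistics (`sorghum_reference_stats()`).
  Truncation is by rejection, which is exact; note that truncating at the
  published bounds *biases* the raw moments (whole-grain starch truncates
  at +1.99 SD, shifting the mean by about −5 g kg⁻¹), so convergence tests
  compare against the analytic truncated-normal moments
  (`truncnorm_moments()`), not the inputs.
* Spectra as Beer–Lambert mixtures on a 1,557-point grid over
  4,000–10,000 cm⁻¹. The printed instrument description ("4 cm⁻¹
  resolution", 1,557 variables over 6,000 cm⁻¹) is internally
  inconsistent — 4 cm⁻¹ would give 1,501 points — and the variable count
  wins. Each analyte gets 3–5 Gaussian bands at conventional
  C–H/O–H/N–H overtone and combination positions (all with at least one
  band below 9,000 cm⁻¹, where grain absorption peaks), scaled so a mean
  mixture spans ≈ 0.25–0.43 absorbance. Ash has no true NIR absorbance;
  its bands are documented stand-ins needed for identifiability.
* A **closed mixture**: the renderer adds a residual-matrix component
  (moisture, soluble sugars, pentosans not captured by the eight assays)
  at concentration `total_mass − Σ analytes` with broad water-band
  absorptivities (`background_model()`, total 1,600 g kg⁻¹ — above the
  largest achievable assay sum, since the overlapping assays double-count
  mass). This matters: without closure the generator emulates a material
  whose total mass varies freely, and scatter correction then *deletes*
  genuine composition information (the fitted MSC slope correlates ≈ 0.9
  with starch), capping validation R² near 0.78 no matter how many latent
  variables are used. Real grains are closed mixtures, which is exactly
  why MSC/SNV are harmless on real spectra. The bare open-mixture
  renderer remains available via `background = NULL` and is exactly
  linear and homogeneous in the concentrations.
* Measurement effects per sample: multiplicative scatter
  b ~ exp(N(0, 0.08²)), additive offset a ~ N(0, 0.01²), linear baseline
  tilt t ~ N(0, 0.01²), and i.i.d. noise of 2×10⁻⁴ AU — a typical
  benchtop FT-NIR noise floor. Whole grains get twice the
  scatter/offset/tilt spread of flours (hull and particle-size
  scattering), which is the motivation for scatter correction in the
  first place.

What it does **not** emulate: instrument line shapes, wavelength-dependent
pathlength, temperature/moisture band shifts, analyte cross-correlations
(identity by default; a user matrix is accepted), or nonlinear
detector effects. A green end-to-end test therefore establishes that the
pipeline recovers composition from data satisfying its own model
assumptions — not that any instrument meets them.

## Numerical and design choices

* **"52 smoothing points"**: an even SG window cannot be symmetric; the
  shipped default is the nearest odd window, 51 points, polynomial order
  2, exposed in every recipe. The "Norris derivative by means of SG" of
  the source treatments is implemented as the SG derivative; a true
  Norris gap-segment derivative is offered separately (`norris_gap()`)
  but is not the default, because the two are conflated in the source and
  the SG form is the reproducible one.
* Derivatives are per index step, not per cm⁻¹; on an even grid this only
  rescales coefficients. SG edges are handled by evaluating the terminal
  polynomial fits, so output length equals input length.
* **R² convention**: squared Pearson correlation of predicted vs
  measured, matching scatter-plot usage and commercial NIR software;
  `r2_method = "sse"` gives 1 − SSE/SST.
* RPD denominators are the corresponding subset SDs (n − 1): calibration
  SD for RPDcv, validation SD for RPDv.
* NIPALS with one response needs no inner iteration; components stop
  early if the response deflates below 10⁻¹⁴, and coefficients are
  β = W(PᵀW)⁻¹q on the original (selected) variables.
* CARS uses 50 runs, 80% Monte-Carlo sampling, a fixed latent-variable
  count per run, and 5-fold RMSECV inside `run_pipeline()` (the
  leave-one-out original is available; 5-fold is indistinguishable here
  and much faster). The recovery benchmark in the tests uses n = 98
  calibration samples — the panel size of the emulated study — with 10
  informative variables out of 200 at a signal-to-noise ratio of 20.
* Outlier screening standardizes scores per component and uses the χ²(2)
  ellipse rather than two per-axis intervals — the standard chemometric
  reading of a "95% confidence interval of the first two PCs". Screening
  runs on the treated full set before splitting, matching the
  remove-then-recalibrate orchestration.
* Noise-robustness levels in the acceptance suite (10⁻³, 10⁻², 10⁻¹ AU)
  were fixed a priori as quiet/moderate/severe for FT-NIR absorbance.

## Known limitations

* The published R²/RPD values of the original study are not reproducible
  because the raw spectra were never deposited; the package's tests
  instead verify the arithmetic identities recomputable from the printed
  tables and the behaviour of each algorithm against independent oracles.
  Several printed cells are internally inconsistent at their own 2-decimal
  precision (mostly low-magnitude tannin/fat rows where a rounded RMSE of
  0.05 is too coarse); these are listed explicitly in the test suite.
* The published per-sample classification supplement is unavailable, so
  the printed grade counts (14/21/38/25) are not an acceptance target —
  though the default simulated world lands within a few samples of them.
* The combined feed/fuel class rule (tannin < 15, hemicellulose ≥ 50) and
  the conservative fuel assignment for the residual case
  (tannin ≥ 15, hemicellulose < 50) are reconstructions; the source text
  does not state either rule explicitly.
* PLSR is linear; strongly nonlinear detector or moisture effects are out
  of scope, as are JCAMP/SPC instrument formats and spectral resampling
  between instruments.
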