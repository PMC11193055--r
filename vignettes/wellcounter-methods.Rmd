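---
title: "Counting nuclei and quantifying cytotoxicity with wellcounter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting nuclei and quantifying cytotoxicity with wellcounter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellcounter)
```

## The screening problem

A plate-based viability assay stains all nuclei with a cell-permeant DNA dye
(Hoechst 33342) and dead nuclei with a membrane-impermeant one (propidium
iodide, PI): every nucleus is visible in the Hoechst channel, and only
late-apoptotic or necrotic nuclei in the PI channel.  Each well of a 96-well
plate is imaged at 10x magnification — either whole or as 12 tiles acquired
in a meandering (serpentine) order and reassembled — and the per-well counts

* total nuclei (Hoechst-positive),
* dead nuclei (PI-positive),
* viable = max(0, Hoechst − PI)

feed everything downstream: proliferation fold changes over a 0 h seeding
control plate, survival/killing rates of treated wells against untreated
controls, and dose-response curves with an ED50.

`wellcounter` implements this pipeline end to end, plus a synthetic image
generator with known ground truth so that every stage is testable without a
microscope.

## Nucleus detection

Detection is scale-normalised Laplacian-of-Gaussian (LoG) blob detection on
preprocessed images:

1. **Unit scaling.**  Images are converted to grayscale (Rec.709 weights for
   colour input) and scaled to [0, 1] by the dtype maximum.  The detection
   threshold below is only meaningful on this scale, so scaling is mandatory
   at ingest.
2. **Well masking.**  Pixels outside the known well disk are replaced by the
   mean of the original image, so the dark plate area cannot generate edge
   responses far brighter than any nucleus.  The disk comes from the plate
   configuration; it is not inferred from intensities.
3. **Median smoothing.**  A 4 x 4 median filter.  An even window has no
   canonical centre: we anchor it with the extra row/column toward increasing
   index (the window at pixel *i* spans *i−1 … i+2*), use the sample median
   (mean of the two middle order statistics), and reflect at borders.  These
   choices are pinned so results are bit-reproducible.
4. **LoG response.**  For each of `num_sigma = 10` scales evenly spaced on
   [1.5, 4] px, the response is the negative scale-normalised LoG,
   −σ²·∇²(G_σ∗I), computed with separable Gaussian / second-derivative
   kernels (support 4σ, reflected borders, zero-sum second-derivative kernel
   so flat images give exactly zero).  A bright spot of Gaussian scale *s*
   peaks at σ ≈ *s* with response ≈ half the spot amplitude.
5. **Maxima.**  Candidates are strict local maxima of the (y, x, σ) response
   volume with response ≥ `threshold = 0.005`; plateau ties go to the lowest
   (y, x, σ) lexicographic index, and border maxima are kept
   (`exclude_borders = FALSE`).
6. **Overlap pruning.**  Each blob is modelled as a disk of radius σ√2.
   Blobs are visited in priority order (larger σ, then higher response, then
   lower (y, x)) and kept only if they overlap every kept disk by at most
   `overlap = 0.35` of the smaller disk's area.  The greedy order makes
   pruning deterministic and idempotent.

When well geometry is supplied, `count_image()` additionally ignores blobs
within `rim_guard_px = 6` px of the well rim: the step between the well
interior and the mask fill always leaves a ring of edge responses at the rim
(their inner peaks sit at distance σ ≤ 4 px inside the rim), and cells at
the very rim of a round well are not reliably imaged anyway.  The synthetic
generator keeps nucleus centres `rim_margin_px = 8` px inside the rim, so
the guard never discards a true nucleus.

Counting always runs on the reassembled well image, not per tile: with
border maxima kept, per-tile counting would double-count nuclei straddling
tile seams.

## The synthetic scene generator

`generate_scene()` draws nucleus centres uniformly in the well disk by dart
throwing with a minimum centre separation (default 8 px; random sequential
adsorption makes densities beyond ~55% disk coverage infeasible, and the
error says so).  Each nucleus gets a radius (uniform in 2.1–5.7 px), a peak
intensity (uniform in 0.3–0.9) and a live/dead flag; exactly
`round(n_cells * dead_fraction)` nuclei are dead.  `render_channels()` draws
each nucleus as an isotropic Gaussian spot with sd = radius/√2 — chosen over
a hard disk because the LoG response of a Gaussian is analytically
predictable, which gives closed-form oracles for the detector tests — adds
Gaussian pixel noise, clips to [0, 1], and sets pixels outside the well to a
dark out-of-well level so the masking stage is genuinely exercised.  Dead
nuclei have the same Hoechst intensity as live ones; the pipeline subtracts
counts, not intensities.

Defaults and their reasoning:

* `radius_range_px = c(2.1, 5.7)`: spot scales (sd 1.5–4 px) spanning
  exactly the detector's σ grid.
* `noise_sd = 0.005` (unit scale, ≈330 grey levels on a 16-bit camera):
  typical background noise of sub-second fluorescence exposures after flat
  background subtraction.
* `background_level = 0.05`, `out_of_well_level = 0`.
* `peak_range = c(0.3, 0.9)`: well-exposed but unsaturated nuclei.

What the generator does **not** model: illumination gradients and
vignetting, Poisson shot noise (count accuracy, not photometry, is the
target), clumped colony growth, out-of-focus tiles, and real chromatin
texture.  Passing tests on these scenes therefore demonstrate algorithmic
correctness and calibration, not robustness to every real-image artifact.

## Measured detection envelope (a known limitation)

Two empirical facts about the reference detection parameters, both
reproduced by the test suite and the reproduction script:

* **Noise.**  The fixed response threshold 0.005 sits only ~3σ above the
  LoG response fluctuations of median-filtered pixel noise of sd 0.02, so at
  that noise level background maxima cross the threshold in large numbers
  (precision collapses to ~0.4 on 800 x 800 fields; the
  `detection_accuracy_study()` at `noise_sd = 0.02` in the reproduction
  script shows this).  At `noise_sd ≤ 0.005` the same study measures
  precision and recall ≥ 0.98.  Users with noisier images should raise
  `threshold` rather than trust the default.
* **Resolution.**  Two nuclei merge in scale space when their separation is
  below roughly 2.5x the spot sd: with the default radius range (sd up to
  4 px), 8 px separations lose ~3% of nuclei even without noise; at 12 px
  separation recall is 1.0.  This is the LoG resolution limit, not a
  tunable; the package deliberately does not attempt watershed splitting of
  touching nuclei.

## Dose-response models and ED50

Survival fractions (treated viable counts over the mean untreated viable
count at the same timepoint; the ratio-of-group-means convention, with the
mean-of-paired-ratios alternative reported alongside) are fitted with two
families:

* **EXD3**, three-parameter exponential decay:
  f(x) = c + (d − c)·exp(−x/e);
* **LL4**, four-parameter log-logistic:
  f(x) = c + (d − c) / (1 + exp(b·(ln x − ln e))), with the analytic dose-0
  limit (d for b > 0) so dose-0 wells need no special casing.

Fitting is Levenberg–Marquardt least squares from data-driven starts
(d = max response, c = min response, e = the dose whose mean response is
nearest the half-range, b = 1) plus three multiplicatively jittered restarts
(±20%, seeded) — LL4 surfaces are multimodal on noisy small-n data — keeping
the best converged RSS; `e` is bounded positive.  Convergence is reported
honestly; there is no silent fallback.

The families are compared by Gaussian-likelihood AIC,
n·ln(RSS/n) + 2(k + 1), counting the error variance as a parameter; the
lower AIC wins and near-ties (|ΔAIC| < 1e−9) go to the smaller model.  Any
consistent AIC convention ranks identically at equal n; this one is the
standard nonlinear-regression form.

ED50 is defined against the fitted asymptotes: the dose where the curve is
midway between d and c.  For LL4 that is `e` exactly; for EXD3, solving
c + (d−c)e^{−x/e} = (c+d)/2 gives x = e·ln 2.  A degenerate fit (c ≥ d for
EXD3) refuses to report an ED50 rather than extrapolate.  The 95% interval
is a nonparametric bootstrap (B = 999, seeded): responses are resampled with
replacement within each dose, the same family is refitted from the point
estimates (single start — the resampled surface is close to the original, and
this keeps 999 refits fast), and the percentile interval is taken.  The
bootstrap was chosen over the delta method because plate experiments have
few replicates; the delta interval is reported alongside for comparison.
On noise-free data the bootstrap interval collapses onto the point estimate.

At the desk-scale study design used by the tests (7 doses 0.5–50 µM, 3
replicates, response noise sd 0.05, LL4 truth with b = 1 and e = 5 µM), the
inherent least-squares precision of `e` gives a median relative ED50 error
of ~12–14%; an exhaustive profiled grid search attains the same optima, so
this is a property of the design, not of the optimizer.  Bootstrap coverage
measures ~86–87% at a nominal 95% — the usual small-n percentile-bootstrap
undercoverage.

## Statistical layer

* `ks_normality()`: one-sample Kolmogorov–Smirnov test against a normal with
  mean/sd estimated from the sample, asymptotic p.  Estimating the
  parameters makes the nominal p conservative (the Lilliefors caveat); the
  result carries that flag explicitly instead of silently substituting a
  different test.
* `bonferroni()`: p_adj = min(1, m·p).
* `tukey_hsd()`: Tukey–Kramer all-pairs comparisons with pooled within-group
  variance, the Kramer SE for unequal n, p-values and family-wise intervals
  from the studentized range distribution (base R's `ptukey`/`qtukey`, the
  canonical numerical integration of that CDF).  The suite cross-checks it
  against `stats::TukeyHSD` on an `aov` fit and against the two-group
  identity q = |t|√2, and verifies the family-wise error rate under a
  simulated null stays near the nominal 0.05.
* `agreement_model()`: OLS of manual on software counts, with slope and
  intercept CIs (t, df = n − 2), R², adjusted R², and the standardized beta
  from refitting on z-scored variables.  Perfect agreement is slope 1,
  intercept 0, R² = 1.
* Report formatting maps p < 0.05 / 0.01 / 0.001 to * / ** / ***; p < 0.05
  is the significance convention throughout.

Where the choice between Bonferroni and Tukey HSD matters, both are exposed
and neither is auto-selected.

## Reproducibility and problem sizes

Every random quantity flows from an explicit integer seed (`with_seed`
sandboxes the RNG state; per-well and per-simulation seeds are derived
deterministically from the master seed), so identical inputs give
bit-identical images, counts and reports.  The bundled studies run at desk
scale — 20 scenes of 800–2,000 nuclei for detection accuracy, 10 clean
scenes for live/dead conservation, 100 simulations (B = 999) for ED50
recovery, 2 x 100 for AIC selection, 1,000 nulls for the family-wise error —
sizes chosen so the whole validation reruns in a few minutes on one core.

## Interfaces

Plate layouts are CSV (`well,cell_line,treatment,dose_uM,timepoint_h,
replicate,role`); images are 16-bit grayscale TIFF named
`<well>_<channel>[_tile<k>].tif` with a JSON manifest carrying seed and well
geometry; counts are CSV (`well,hoechst,pi,viable`); analysis reports are
CSV plus JSON.  The `inst/cli/wellcounter` script exposes `simulate`,
`count` and `analyze` subcommands whose flags mirror `detection_params()`
with the reference defaults.
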