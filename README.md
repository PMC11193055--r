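# wellcounter

Automated viability and cytotoxicity screening from two-channel fluorescence
images of 96-well plates, for labs that count cells instead of titrating
colorimetric proxies.  All nuclei are stained with Hoechst 33342, dead nuclei
with propidium iodide (PI); `wellcounter` counts both channels, derives
viable counts, proliferation fold changes and killing rates from a plate
layout, fits dose-response curves and reports the median effective dose
(ED50).  A bundled synthetic-image generator with known ground truth makes
the whole pipeline testable without a microscope.

## Method

Nuclei are detected as maxima of the scale-normalised negative
Laplacian-of-Gaussian response

&nbsp;&nbsp;&nbsp;&nbsp;R(y, x; σ) = −σ² · ∇²(G_σ ∗ I)(y, x)

over 10 scales σ ∈ [1.5, 4] px, after masking everything outside the well
disk with the image mean and median-smoothing with a 4 × 4 window.  Strict
local maxima of the (y, x, σ) volume with R ≥ 0.005 (on unit-scaled
intensities) become blobs; overlapping blobs (model disks of radius σ√2,
overlap fraction > 0.35 of the smaller disk) are pruned, coarser scale
first.  Per well,

&nbsp;&nbsp;&nbsp;&nbsp;viable = max(0, N_Hoechst − N_PI),

survival is the ratio of group means versus untreated controls, killing is
1 − survival, and survival-vs-dose data are fitted with both a
three-parameter exponential decay, f(x) = c + (d−c)·e^(−x/e), and a
four-parameter log-logistic, f(x) = c + (d−c)/(1 + exp(b(ln x − ln e))).
The model with the lower AIC (n·ln(RSS/n) + 2(k+1)) is selected; ED50 is e
for the log-logistic and e·ln 2 for the exponential family, with a 95%
bootstrap percentile interval (B = 999, responses resampled within dose).

See `vignettes/wellcounter-methods.Rmd` for assumptions, parameter
reasoning, numerical conventions and measured limitations.

## Worked example

```r
library(wellcounter)

## a synthetic well: 800 nuclei, 20% dead, imaged at 900 x 1200 px
scene    <- generate_scene(800, dead_fraction = 0.2, seed = 42)
channels <- render_channels(scene)
count_well(channels$hoechst, channels$pi,
           well_center_xy = scene$well_center_xy,
           well_radius_px = scene$well_radius_px)
#>   well hoechst  pi viable
#> 1 <NA>     779 158    621
```

779 of 800 nuclei are found (nuclei closer than ~2.5× their spot scale merge
in scale space), 158 of 160 dead ones, and the viable count 621 tracks the
true 640 within 3%.

```r
## dose-response on simulated survival fractions (log-logistic truth, e = 5)
dat <- simulate_dose_response("LL4", c(b = 2.5, c = 0.05, d = 1, e = 5),
                              noise_sd = 0.03, seed = 7)
fit <- select_model(dat, seed = 7)
fit
#> <dose_response_fit> LL4, n = 21, converged
#>   estimate std_error
#> b  2.45721   0.29647
#> c  0.05320   0.02279
#> d  0.98959   0.01914
#> e  5.53067   0.27163
#> RSS = 0.0162462, AIC = -140.4528

round(attr(fit, "aic_both"), 2)    # AIC picks the log-logistic here
#>    EXD3     LL4
#> -119.05 -140.45

ed50(fit, seed = 7)[c("ed50", "ci")]
#> ED50 = 5.53 uM, 95% bootstrap CI [5.18, 5.82]
```

The ED50 estimate (5.53 µM) recovers the simulated truth (5 µM) within the
interval's width; `plot(fit)` draws the curve on a log-dose axis with the
ED50 marked by a triangle.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/wellcounter simulate --out demo --wells 2 \
        --cells-per-well 800 --dead-fraction 0.2 --seed 4
Rscript inst/cli/wellcounter count --images demo --out demo/counts.csv
Rscript inst/cli/wellcounter analyze --counts demo/counts.csv \
        --layout layout.csv --out demo/report
```

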