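---
title: "Calibrating NIR spectra to rubber content in dried dandelion roots: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating NIR spectra to rubber content in dried dandelion roots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

*Taraxacum kok-saghyz* (rubber dandelion) synthesizes natural rubber
(cis-1,4-polyisoprene) in its roots and is a candidate alternative to
*Hevea* rubber. Breeding programs need to rank thousands of individuals by
root rubber content, but the wet-chemistry reference assay (alkali boiling)
is slow and destructive. Near-infrared diffuse-reflectance spectroscopy of
dried roots — as cut segments or ground powder — offers a rapid surrogate,
provided a calibration model maps the 850–2500 nm absorbance spectrum to
rubber content (% of dry mass).

`nircal` implements the full chemometric workflow for building and judging
such calibrations:

1. **Outlier screening** by Monte-Carlo subsampling (`mcs_screen()`);
2. **Spectral pretreatment** chains from moving-window smoothing (MWS),
   standard normal variate (SNV), multiplicative scatter correction (MSC)
   and the first derivative (FD) (`fit_chain()`, `apply_chain()`);
3. **Sample-set partitioning** at 3:1 by SPXY or Kennard–Stone
   (`spxy_split()`, `ks_split()`);
4. **Wavelength selection** by competitive adaptive reweighted sampling
   (CARS) or the fixed rubber chemical bands (`cars_select()`,
   `chemical_bands()`);
5. **Calibration** by PLS, random forest, leaf-wise gradient-boosted trees,
   or a small 1-D CNN (`fit_pls()` and friends);
6. **Evaluation** by $R^2$, RMSE, RPD and the high-content stratum RMSEP
   (`evaluate_model()`), with `run_experiment()` orchestrating the whole
   grid and `leakage_audit()` certifying that no validation information
   leaked into any train-derived parameter.

Because instrument data of this kind are rarely public, the package ships a
synthetic-spectra generator (`synth_config()`, `simulate_nir_dataset()`)
that emulates the statistical structure of dried-root NIR data closely
enough that every stage of the pipeline can be exercised and its behaviour
verified by parameter recovery.

## The synthetic data model

`render_spectra()` draws, for sample $i$ with rubber content $c_i$ (%),

$$A_i(\lambda) = \mathrm{bg}(\lambda) + \frac{c_i}{100}\,\varepsilon_{NR}(\lambda)
  + \sum_j z_{ij}\,\varepsilon_j(\lambda) + a_i + b_i \lambda,$$

followed by a per-sample scatter distortion $m_i A_i(\lambda) + d_i$ and iid
Gaussian noise. The components:

* **Matrix background** $\mathrm{bg}$: a fixed ~1 AU spectrum of broad
  water/carbohydrate bands (1200, 1450, 1940, 2270 nm) on a gentle slope.
  This term is structural, not cosmetic: dried plant tissue absorbs
  strongly everywhere in the NIR and the analyte is a perturbation on that
  bulk. Without a dominant common background, SNV would normalize the
  analyte signal away entirely (a spectrum proportional to
  $c\,\varepsilon + \text{const}$ is scale-invariant in $c$ after
  per-spectrum standardization), which is unphysical.
* **Analyte signature** $\varepsilon_{NR}$: Gaussian peaks at 1180, 1660,
  1720, 2240 and 2310 nm — inside the three C–H overtone/combination
  windows (1100–1250, 1550–1760, 2100–2400 nm) where cis-polyisoprene
  absorbs. Peak positions within the windows are a package choice; only the
  windows themselves are fixed by the chemistry.
* **Interferents**: a few Gaussian-peaked constituents placed anywhere on
  the grid with concentrations independent of $c_i$, so wavelength
  selection faces genuine signal-vs-nuisance structure.
* **Content distribution**: a mixture — with probability 0.35 a uniform
  draw on 0–5% (low-rubber hybrids), otherwise a gamma (shape 5, scale 3.2)
  truncated to [0, 28.7] by inverse-CDF sampling. At large $n$ this gives
  mean ≈ 10.5%, sd ≈ 7.6% and positive skew, matching the descriptive
  statistics of the emulated sample set.
* **Distortions** (defaults; "segment" presets in parentheses): scatter
  multiplier sd 0.08 (0.15), additive offset sd 0.05 (0.08) AU, baseline
  offset sd 0.05 AU and slope sd 5e-5 AU/nm, noise sd 0.003 (0.008) AU.
  Root segments get the harsher preset because their rough surface and
  uneven size degrade diffuse-reflectance repeatability relative to ground
  powder.
* **Gross outliers** (`inject_outliers()`): a configurable minority of
  samples receives either a gross mislabel — the reference value shifted by
  half the content range, wrapping at the maximum, so the mismatch is
  ±14.35% regardless of the original value — or a 0.8 AU artifact block
  over a random 300 nm region.

What the generator does *not* emulate: reference-assay error (labels are
exact, so absolute performance metrics are optimistic relative to real
data), instrument line-shape and wavelength-registration effects,
non-linear scattering physics, and constituent closure (interferent
concentrations do not sum with the analyte to 100%). Passing recovery tests
therefore demonstrates that the algorithms do what they claim on data with
the assumed structure — not that any particular real-world accuracy will be
attained.

## Stage-by-stage notes and tunables

### Spectra handling

Spectra live in a wide tibble (`id` + one column per wavelength in nm).
`resample_spectra()` reduces a fine instrument grid by non-overlapping
block means labeled by the block-left wavelength; under this half-open
[850, 2500) convention a 3300-point grid at 0.5 nm becomes exactly 825
points at 2 nm, the working resolution used throughout. Block means (not
decimation) are the default because the reduction doubles as noise
averaging; `method = "decimate"` is available for comparison.

### Outlier screen

`mcs_screen()` fits `n_runs = 500` PLS models (fixed `n_components = 8`)
on random 80% subsets and accumulates each sample's held-out errors; MEAN
(mean absolute error) and STD (sd of signed errors) locate each sample in
the screening plane, and a sample beyond either cut is flagged (OR rule).
The defaults give each sample ≈ 100 held-out appearances.

The default cut rule is `median + 8·MAD` per statistic. We deliberately do
not use a mean + 3·sd fence: a handful of gross outliers inflates the mean
and sd of the very statistics the fence is built from and can mask the
outliers themselves — we observed planted mislabels sitting just below
such a contaminated cut. The median/MAD fence is immune to that
contamination, and the wide 8-MAD multiplier keeps false flags rare under
the heavy-tailed errors that raw-spectrum PLS produces. Both cuts carry a
1e-6 %NR numerical floor so that data fitted to machine precision flag
nothing, and `rule = "classic"` or explicit `mean_cut`/`std_cut` values
reproduce other conventions. Signed-vs-absolute error and all run
parameters are configurable because the screening literature fixes none of
them.

### Pretreatment chains

Chains are written as printed in model-comparison tables (`"MWS-SNV"`,
`"MWS-FD"`, ...) and execute left to right. Numerical conventions fixed by
test: MWS uses a 5-point centered window truncated at the spectrum edges
(width preserved); SNV divides by the sample (n−1) standard deviation; FD
is the plain successive difference divided by the grid step, on a midpoint
grid (MWS already supplies the smoothing a Savitzky–Golay derivative would
add); MSC regresses each spectrum on the *training* column-mean reference
and inverts the fitted affine distortion. `fit_chain()` records the MSC
reference so `apply_chain()` applies identical, train-derived parameters to
validation data.

### Splitting

`spxy_split()` uses the joint distance
$d_{ij} = d^x_{ij}/\max d^x + d^y_{ij}/\max d^y$, seeds the training set
with the most distant pair and grows it by the max–min rule. Ties break to
the lowest sample index, making the split bit-reproducible across
platforms; the training size is `round(ratio·n)` rounding half up (125 →
94/31, 117 → 88/29 at 3:1); a constant-$y$ panel makes the $d^y$ term zero,
reducing SPXY to Kennard–Stone exactly.

Distances are computed on the pretreated spectra actually used for
modeling, so the pipeline splits *after* preprocessing. That creates a
chicken-and-egg problem for MSC, whose reference must come from training
rows only. `run_experiment()` resolves it in two passes: the split is
computed on provisionally processed spectra (MSC self-referenced on all
post-screen rows), then the modeling chain is refit on the training rows
alone. The audit trail records the refit reference, and `leakage_audit()`
recomputes it from stored data to prove no validation row contributed.

### CARS

Each of `n_runs = 50` Monte-Carlo runs fits PLS on a random 80% of the
training samples, converts coefficients to weights $w_j = |b_j|/\sum|b_j|$,
applies the exponentially decreasing function (EDF) that forces the
retained count from $p$ (run 1) down to 2 (run $N$) — constants
$a = (p/2)^{1/(N-1)}$, $k = \ln(p/2)/(N-1)$ — and then resamples the
survivors: $\lceil r_i p\rceil$ weighted draws with replacement, distinct
survivors retained (`ars = FALSE` gives the deterministic top-weight cut
instead). When the weighted draw degenerates below two distinct variables,
the set is topped up with the highest-weight forced variables to the
2-variable floor the schedule itself guarantees. Each run's subset is
scored by 5-fold RMSECV with seed-fixed folds, and the minimum-RMSECV
subset wins. The PLS component count inside CARS equals the count used for
the final model of that configuration, and the per-run trace (retained
counts, RMSECV, coefficients) is kept for plotting.

ARS is genuinely stochastic: a mildly informative variable can fail to be
drawn in an early run and is then gone for good. Recovery statements about
CARS are therefore made as medians over a few seeds, not per-seed
guarantees.

### Calibration families

* **PLS** (NIPALS, single response, written in-package because CARS, the
  screen and every RMSECV need cheap refits and coefficient paths): by
  default the component count minimizes 10-fold RMSECV over 1–15, a cap
  that covers the counts typical for this material. Verified in the test
  suite against ordinary least squares at full rank, a power-iteration
  oracle for the first latent variable, and an independent NIPALS
  implementation.
* **RF**: 200 naturally grown trees via `randomForest`.
* **GBT**: leaf-wise boosting with learning rate 0.1, ≤ 30 leaves,
  unlimited depth — run on `xgboost` with `grow_policy = "lossguide"`, the
  same leaf-wise strategy LightGBM introduced; remaining settings stay at
  library defaults and are recorded on the model.
* **CNN**: conv(16 kernels × 20, stride 10) → ReLU → maxpool(3, stride 1)
  → dense(64, ReLU) → linear, trained by *full-batch* SGD on MSE at
  lr = 0.01. Full-batch makes training deterministic given the seed and
  invariant to sample order. Inputs are standardized per wavelength and the
  response internally standardized (training statistics stored on the
  model) — without response scaling the quadratic loss surface at lr 0.01
  is unstable. Weights use LeCun-scaled init (sd $1/\sqrt{\text{fan-in}}$);
  He init overshoots in the first epochs at this learning rate. The
  protocol default is 20000 epochs; grid runs and tests use far fewer (30–
  200), which on the synthetic material already reaches the loss plateau.
  The 64-unit head and init scheme are package choices recorded in the
  model's hyperparameters.

Predictions are reported as-is; negative predictions are not clipped.

### Evaluation

$R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$,
$\mathrm{RMSE} = \sqrt{\tfrac1n\sum(y-\hat y)^2}$, and
$\mathrm{RPD} = \mathrm{sd}(y_{val})/\mathrm{RMSEP}$ with the sample (n−1)
sd — the definition the conventional screening thresholds (RPD > 2 usable,
> 3 good) refer to. A variant sometimes printed in the applied literature,
$\sum(y-\bar y)^2/\mathrm{RMSE}$, is dimensionally inconsistent with those
thresholds; it is available as `metric_rpd(..., literal = TRUE)` for
comparison but never used in reports. The high-content stratum RMSEP uses
the strict cutoff $y > 15\%$, the range that matters when screening for
high-rubber individuals.

## Problem sizes

The test suite and the acceptance script run entirely on generated data at
desk scale, chosen to exercise every code path with comfortable margins:
calibration sets of 40–130 samples on grids of 100–825 wavelengths
(3300 for the resampling check), 500-run screens for recovery claims and
100–200-run screens elsewhere, CARS at 30–50 runs on 200–400 wavelengths,
and CNN fits of 30–200 epochs. The experiment grid in the pipeline tests
covers 2 band methods × 4 families × 5 chains = 40 configurations.

## Known limitations

* The generator's linear-mixture optics plus affine scatter are a
  first-order model; SNV/MSC can correct them almost exactly, so absolute
  metrics on synthetic data exceed what real dried-root spectra allow.
  Directional findings (preprocessing helps; screening helps; powder beats
  segment) are the transferable quantities.
* The CNN is a faithful small implementation, not a tuned deep-learning
  model; with full-batch SGD and no regularization it is adequate for
  architecture-level checks and modest grids.
* `mcs_screen()` detects samples whose *predictions* misbehave; an x-space
  anomaly that projects weakly onto the calibration (e.g. an artifact in a
  chemically silent region) can evade a prediction-error screen.
* SPXY places both content extremes in the training set on most but not
  every dataset — with joint x–y distances an extreme-y sample that is
  x-close to an already selected one can be passed over.
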