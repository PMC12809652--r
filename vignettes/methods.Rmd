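---
title: "Calibrated uncertainty for SERDS spectral regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated uncertainty for SERDS spectral regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(serdsuq)
```

## The problem

Estimating soil organic carbon (SOC, % by mass) from Raman spectra of soil
is hard for two structural reasons. First, organic matter and microbial
residues fluoresce strongly under near-infrared excitation, so the Raman
signal of interest rides on a background of much greater intensity. Shifted
excitation Raman difference spectroscopy (SERDS) addresses this by
acquiring each measurement with two closely gapped lasers: Raman bands
shift with the excitation wavelength while fluorescence does not, so the
difference of the two channels cancels the background and leaves a
derivative-like Raman signature. Second, even after fluorescence rejection,
mineral-organic diversity and albedo (reflectance) effects mean different
soils can produce similar spectra — the map from spectrum to SOC is weakly
multimodal, and predictions carry irreducible, input-dependent (aleatoric,
heteroscedastic) uncertainty.

A point estimate is therefore not enough for decision-critical use; what is
needed is a *calibrated*, per-sample uncertainty. This package implements a
complete, testable version of that workflow: a synthetic dual-laser SERDS
generator, the standard preprocessing chain, five neural uncertainty
quantification (UQ) heads on a shared 1D-CNN backbone, split-conformal
calibration of any of them, and an evaluation suite.

## Split-conformal calibration

Every UQ model here exposes the same contract: for an input spectrum $x$ it
returns $(\hat y, \hat\sigma)$, a point prediction and a heuristic standard
deviation. Under a Gaussian-residual assumption the heuristic 90% interval
is $\hat C(x) = [\hat y - z\hat\sigma,\, \hat y + z\hat\sigma]$ with
$z = \Phi^{-1}(0.95) \approx 1.64$.

On a held-out calibration set of $n$ i.i.d. pairs $(x_i, y_i)$ never seen
in training, the nonconformity score of each pair is the signed distance
from the truth to the nearest interval edge,

$$s(x_i, y_i) = \max\{\, y_i - (\hat y_i + z\hat\sigma_i),\;
(\hat y_i - z\hat\sigma_i) - y_i \,\},$$

negative inside the interval and positive outside. The calibration quantile
is the $k$-th smallest score with $k = \lceil (n+1)(1-\alpha) \rceil$
(`conformal_quantile()`); the calibrated interval is

$$C(x) = [\hat y - z\hat\sigma - \hat q,\; \hat y + z\hat\sigma + \hat q].$$

This guarantees $P(y \in C(x)) \ge 1 - \alpha$ marginally for a fresh pair
from the same distribution, *regardless of how miscalibrated*
$\hat\sigma$ is — the package's acceptance suite demonstrates this with a
base model whose $\hat\sigma$ is deliberately halved. For continuous scores
the coverage is also upper-bounded by $1 - \alpha + 1/(n+1)$.

Three boundary conventions are fixed deliberately:

* **$k > n$ sentinel.** If the calibration set is too small for the
  requested level, $\hat q = +\infty$ and intervals are unbounded. This
  preserves the guarantee rather than silently falling back to the maximum
  score. With the default $n = 100$, $\alpha = 0.1$, $k = 91 \le n$ and the
  sentinel never triggers.
* **Calibrated SD.** The adjustment folds into the predicted SD as
  $\sigma = \hat\sigma + \hat q / z$. The division by $z$ is chosen so that
  $\hat y \pm z\sigma$ is *algebraically identical* to $C(x)$ (verified
  numerically in the tests); intervals at other levels $L$ are rebuilt as
  $\hat y \pm z_L \sigma$, which is exact only under Gaussian residuals —
  an assumption, not a guarantee, and documented as such.
* **Negative $\sigma$.** A strongly negative $\hat q$ can push
  $\hat\sigma + \hat q/z$ below zero (upper bound below lower). The value is
  clamped to zero with a warning; the raw value is kept in an attribute.
* **Ties** are handled by taking the $k$-th order statistic under a stable
  sort, which matches the brute-force sort-and-index oracle by
  construction.

## The synthetic generator

No public SERDS soil dataset exists, so the generator is a first-class,
tested module that emulates the statistical structure the pipeline relies
on — it is explicitly *not* a physical instrument model. Per sample:

* a latent SOC is drawn uniformly over `soc_range` (default 0.28–6.95 %,
  the observed range for the reference task; the uniform prior is a
  documented choice, configurable);
* the recorded label adds heteroscedastic noise
  $N(0, (c_0 + c_1\,\mathrm{soc})^2)$ with default $c = (0.1, 0.05)$ % SOC —
  the irreducible label-conditional uncertainty that deterministic UQ heads
  should learn;
* organic Raman bands (aromatic ring breathing 1003, carbohydrate C–O
  1090, disordered-carbon D band 1340, CH$_2$ 1450, aromatic C=C G band
  1600, amide I 1660 cm$^{-1}$) have amplitudes following the saturating
  law $a(\mathrm{soc}) = a_{\max}\,\mathrm{soc}/(\mathrm{soc}+3)$ —
  monotone but deliberately nonlinear; two SOC-independent mineral bands
  (465, 1085 cm$^{-1}$) are added; laser 2's Raman component is laser 1's
  translated by the laser gap (default 10 cm$^{-1}$), which is the SERDS
  premise;
* fluorescence is a low-order polynomial plus a broad Gaussian hump,
  peak-scaled to `fluorescence_amplitude_ratio` (default 10) times the
  unit Raman amplitude, near-identical across the two lasers up to a small
  multiplicative tilt (2%), so common-mode rejection has a realistic shared
  background to remove. Its shape parameters are derived from the latent
  SOC by low-discrepancy scrambling (golden-ratio multiples mod 1): they
  vary erratically between samples — carrying no usable smooth information
  about SOC — while keeping the clean measurement a deterministic function
  of SOC, which pins down the generator's reproducibility contract
  (equal SOC, zero albedo spread, zero noise ⟹ identical measurements);
* an albedo-like confounder multiplies the whole signal by a per-sample
  log-normal factor (default log-SD 0.2). Because multiplicative scatter
  correction (MSC) operates *within* each replicate set, this factor
  survives preprocessing and makes spectrum–SOC matching ambiguous, the
  multimodality the task is known for;
* measurements add a constant dark offset and per-replicate Gaussian
  intensity noise, and scale with the integration time (default 200 ms).

Desk-scale defaults are a 3×3 grid, 3 replicates per laser and 300
samples; `full_scale_config()` provides the full acquisition protocol
(10×10 grid, 15 replicates, i.e. 3000 measurements per sample). What the
generator does **not** emulate: real Raman cross-sections, detector
nonlinearity, cosmic rays, wavelength drift, mineral libraries, spatial
correlation across the grid. Passing tests on this generator therefore
demonstrate correctness of the *algorithms* and the conformal guarantee —
not instrument-level performance on real soils.

## Preprocessing chain

`preprocess_sample()` runs, in fixed order: MSC across each replicate set →
replicate averaging + integration-time normalisation → per-grid-position
common-mode rejection → SERDS difference (laser 2 − laser 1) → grid
averaging → Savitzky–Golay smoothing (window 11, order 2) → linear
resampling onto the uniform model grid.

Numerical choices worth knowing:

* **1650 channels.** A 350–2000 cm$^{-1}$ grid at 1 cm$^{-1}$ contains 1651
  points inclusive; the model input is defined as 1650 channels, so the
  grid is half-open $[350, 2000)$. This reconciliation is asserted in the
  tests.
* **MSC reference.** With `reference = "mean"` the mean spectrum is
  normalised to *unit mean intensity* before fitting. The classic
  mean-spectrum reference leaves a global intensity scale in the output;
  the normalisation makes the whole chain invariant to uniform scaling
  (a property the tests check). An explicit reference is used as-is, so a
  spectrum equal to the reference maps to itself. Slopes with
  $|b| < 10^{-8}$ raise a degenerate-spectrum error naming the offender.
* **Common-mode rejection.** The published variant of this step is not
  fully specified by its source; here each channel's smooth background is a
  multi-level Daubechies-4 wavelet approximation (detail coefficients
  zeroed up to `cmr_levels`, default 6, i.e. a ~64-point scale at the
  native step), the laser-2 background is regressed on the laser-1
  background (scale + offset), and the fitted shared component is
  subtracted from both. This is a faithful-in-spirit reimplementation; no
  bit-equivalence with any external implementation is claimed. The DWT is
  written in-package (periodic, reflection-padded) and verified by exact
  round-trip reconstruction.
* **Savitzky–Golay edges** use the filter's asymmetric full-window
  polynomial fits at the boundaries (the `signal` package's transient
  matrices), so every output point is a local degree-2 fit and polynomials
  of degree ≤ 2 are reproduced exactly everywhere.
* **Order of operations.** Smoothing is applied to the grid-averaged
  difference spectrum (averaged-then-smoothed); the SERDS sign convention
  is laser 2 − laser 1.

## UQ heads and training

All five methods share one backbone: conv blocks (1D convolution → ReLU →
batch normalisation → max pooling) followed by dense blocks (fully
connected → ReLU → dropout) and a linear head. The default (16/32/64
channels, kernel 7, pool 2; dense 128/64, dropout 0.2) is sized for CPU
work and fully configurable. The engine is written in R on BLAS matrix
operations; its reverse-mode gradients are verified against central finite
differences for every layer type and loss in the test suite.

* `het_gaussian`: two outputs (mean, log-SD), Gaussian negative
  log-likelihood. The log-SD head is squashed smoothly to ±6 (standardised
  units) for stability, and the first 30% of epochs train the mean head
  alone (mean-warmup), a standard stabilisation for heteroscedastic
  regression.
* `quantile`: three pinball-loss heads at levels 0.05/0.5/0.95;
  $\hat y$ is the median head and
  $\hat\sigma = (\hat q_{0.95} - \hat q_{0.05}) / (2 \cdot 1.6449)$, making
  the SD directly computable from the inter-quantile span; crossing
  quantiles are clipped to ordering by sorting.
* `mc_dropout`: squared-error backbone; at prediction time 50 stochastic
  passes, each with *one shared dropout mask* (a single thinned-network
  hypothesis per pass, making predictions independent of row order), give
  the mean and sample SD.
* `bayes_backprop`: mean-field Gaussian weight posteriors, single
  scale-free $N(0, \text{prior\_sd}^2)$ prior, one reparameterised posterior
  draw per training step, KL term in closed form weighted $1/n$; prediction
  averages 50 posterior draws.
* `deep_ensemble`: independently initialised squared-error members
  (default 5); prediction is the mean and sample ($n-1$ denominator) SD of
  the member *point* predictions.

Inputs are standardised per channel and labels standardised, with
statistics fit on the training split only and $\hat\sigma$ rescaled back —
leakage-free by construction. Training uses Adam with a two-step 10×
learning-rate decay and optional validation-based checkpointing (15% split,
best-validation weights retained): without it the NLL σ-head overfits the
squared-residual noise. One fixed seed determines initialisation, batch
order, dropout masks and posterior draws, so training and prediction are
bit-reproducible.

The probabilistic heads estimate *epistemic* spread (disagreement among
hypotheses) and are expected to under-cover when the dominant uncertainty
is aleatoric; the deterministic heads learn the aleatoric noise law
directly and are expected to be near-calibrated before conformalization.
The ablation (`ablate_conformalization()`) reproduces exactly this
qualitative pattern on the generator's aleatoric-dominated default data,
and conformalization repairs all of them to the nominal level.

## Evaluation protocol

`uncertainty_report()` collects accuracy ($R^2$, MAE, MAPE, RMSE), 90%
coverage, the coverage curve over levels 5–95% (step 5) plus 99% with its
calibration RMSE, and three uncertainty-quality metrics on the calibrated
SD: sharpness (median SD), consistency (variance of SD) and informativeness
(Pearson correlation between SD and absolute error; flagged `NA`, never
silently 0, when the SD is constant). Boundary values count as covered.
`cross_validate()` implements the representative-model protocol: per fold,
several models are trained each with a fresh random 100-sample calibration
split, and the model with the *median* absolute 90% coverage error is
selected (lower median for even counts — deterministic), so aggregated
results reflect typical rather than best-case behaviour; each dataset
sample receives exactly one aggregated prediction. Statistics on
$\hat\sigma$ are computed on the *calibrated* SD in after-calibration
contexts.

## Problem sizes used in the tests

The test and acceptance runs use desk-scale sizes chosen once: the
conformal-guarantee study uses a fixed band-contrast linear regressor
(σ halved) with 200 replications of 100 calibration + 250–500 test samples
from a single-grid-position generator config; heteroscedastic recovery uses
the known-noise benchmark at $n = 2000$ with a small two-conv-block
backbone; the five-method ablation uses 900 samples on a 330-channel model
grid (5 cm$^{-1}$ step), 100-sample calibration splits and a 300-sample
test block, with 3-member ensembles and 30 Monte-Carlo passes; each head is
hand-tuned separately (epochs, batch size, warmup fraction) so that
accuracies are comparable across methods, the standard practice for method
comparisons. For the
ablation's after-calibration band we use the design's standard error
$\sqrt{p(1-p)(1/n_{\text{test}} + 1/n_{\text{cal}})}$, since one test block
and one trained model per method are involved rather than fully fresh
replications.

## Known limitations

* The backbone is a compact stand-in: the reference task's exact
  architecture and per-method hyperparameters are not public, and no
  exhaustive search is attempted here.
* The quantile head's SD construction is one reasonable reading of
  "directly computable"; other span-to-SD mappings are possible.
* Conformal validity is *marginal*: per-stratum (conditional) coverage is
  not guaranteed, and non-90% levels rebuilt from the calibrated SD rely on
  the Gaussian-residual assumption.
* The generator's fluorescence and noise models are stand-ins; results on
  it validate algorithms, not field performance.
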