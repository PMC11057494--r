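---
title: "Automated all-cycle LVEF estimation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated all-cycle LVEF estimation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echolvef)
```

## The problem and the model

Left-ventricular ejection fraction (LVEF) is the fraction of the diastolic
blood volume ejected per beat,

$$\mathrm{LVEF} = \frac{EDV - ESV}{EDV} \times 100\%,$$

with $EDV$ and $ESV$ the LV volumes at end-diastole (ED, the ventricle at
its largest) and end-systole (ES, at its smallest). Guidelines estimate
these volumes with Simpson's biplane method, which needs two orthogonal
apical views. When only the apical four-chamber (A4C) view is available, the
single-plane **area-length (ellipsoid) model** applies:

$$V = \frac{8 A^2}{3 \pi L},$$

where $A$ is the LV cavity area in the imaging plane and $L$ the LV length
from the apex to the midpoint of the mitral annular plane. For an ideal
ellipse with axes $(L, D)$ the cavity area is $A = \pi L D / 4$ and the
formula reduces *exactly* to the prolate-spheroid volume $\pi L D^2 / 6$ —
this identity is the package's central analytic oracle, and the test suite
asserts it to $10^{-9}$ relative error.

Manual LVEF reading is slow and poorly reproducible, particularly in atrial
fibrillation (AF), where cycle lengths and beat-to-beat EF vary and
guidelines ask for averages over several cycles that are rarely traced in
practice. The pipeline automates the whole chain:

1. **Segmentation** — an atrous convolutional network labels the LV cavity
   in every frame; the area is the foreground pixel count.
2. **Cycle detection** — all ED/ES frames are found by prominence-filtered
   peak detection on the per-frame area curve.
3. **Area refinement** — per-cycle ED/ES areas are stabilised by
   percentile-pooled averaging (the "improved Jeffrey's" scheme).
4. **Length prediction** — a voting ensemble regressor maps mask shape
   features to $L$, because annular/apex landmarks are unavailable at
   inference time.
5. **Volumes, EF, phenotype** — area-length volumes per cycle, EF per
   cycle, the arithmetic mean over all $N$ detected cycles, and the heart
   failure phenotype: HFrEF ($<40\%$), HFmrEF ($40$–$49\%$), HFpEF
   ($\geq 50\%$). The HFrEF boundary is strict: an EF of exactly 40 is
   HFmrEF.

Everything runs in pixel units. EF is a ratio of volumes, so the spatial
calibration cancels algebraically; the suite checks numerically that scaling
areas by $s^2$ and lengths by $s$ leaves every EF unchanged.

A note on the EF formula: written as $(ESV - EDV)/EDV$ it would be negative
for any contracting ventricle. This package uses $(EDV - ESV)/EDV \cdot 100$
throughout, which is the convention all reported EF values (e.g. the
HFpEF/HFmrEF examples below) require.

## The synthetic heart

Clinical echo datasets are large, access-controlled downloads, and training
the full-scale network needs GPU-class hardware. The package therefore ships
a simulator whose outputs have *analytic* ground truth, so that every stage
is testable on any desk:

- The LV cavity is a filled ellipse on a 112×112 canvas (the network's
  input size), with full axes $(L(t), D(t))$.
- Within a cycle the axes follow a raised-cosine contraction profile from
  the ED values down to the ES values and back, with ES placed at 40% of the
  cycle — systole shorter than diastole, which also exercises asymmetric
  peak spacing in the detector.
- The per-cycle EF target is inverted in closed form through an isotropic
  shrink $s$: $L_{es} = sL_{ed}$, $D_{es} = sD_{ed}$ gives
  $\mathrm{EF} = 1 - s^3$, so $s = (1 - \mathrm{EF}/100)^{1/3}$.
- Rhythm: cycle lengths are constant (sinus) or drawn from a log-normal
  with a chosen coefficient of variation (AF-like; defaults 0 and ~0.25–0.3
  in the tests), clipped at 4 frames; explicit period vectors are also
  accepted. A lead-in of 45% of the mean period precedes the first ED, so
  the clip opens just after an end-systole and every true ED is an interior
  area maximum with near-full prominence — as in a clip cut at an arbitrary
  phase.
- Texture: a dark blood pool (0.10), bright endocardial rim (0.85) and
  mid-grey surround (0.40) under multiplicative uniform speckle with
  half-width $\sqrt{3}/\mathrm{SNR}$ (default SNR 8).

```{r sim-example, eval = FALSE}
sim <- simulate_echo(rhythm_spec(3, mean_period = 50, period_cv = 0.3, seed = 1),
                     lv_shape_spec(80, 40, per_cycle_ef = c(55, 48, 60)))
str(sim$truth)
```

What the simulator does **not** emulate: ultrasound physics (no
point-spread function, shadowing, or dropout), valve and atrial anatomy,
probe motion, or out-of-plane foreshortening. Tests passing on this phantom
therefore validate the *quantitative machinery* — peak detection,
refinement, the volume model, the statistics — and the network's capacity to
fit; they say nothing about segmentation accuracy on clinical images, which
is dataset- and training-budget-bound.

## Cycle detection

ED candidates are interior local maxima of the area curve whose topographic
prominence strictly exceeds half of the curve's global range
(`prominence_fraction = 0.5`), kept at least `min_distance = 20` frames
apart (taller peaks win ties); ES candidates come from the same rule on the
negated curve. Each ED is paired with the first ES after it and before the
next ED. The half-range prominence rule makes detection invariant under
positive affine rescalings of the curve, and it is what rejects spurious
bumps from segmentation noise: the suite injects spikes of 0.3×range and
checks the cycle count never changes. A constant curve, or one shorter than
`2 * min_distance`, yields an empty cycle set with a warning rather than an
error, and the pipeline reports `"insufficient cycles"` in that case.

The 20-frame separation is interpreted as the minimal frame distance between
retained extrema — at typical acquisition rates this is comfortably below
one cardiac cycle, and it is exposed in `peak_params()` for other frame
rates.

## Area refinement (percentile pooling)

A single corrupted frame at an ED or ES position propagates directly into
that cycle's EF. The refinement replaces the raw single-frame area at a
cycle's ED with the mean of a pooled multiset: the raw value itself, the top
`ceiling(0.10 * n)` areas of the whole curve, and the top
`ceiling(0.10 * m)` areas among the frames from that cycle's ED to its ES
inclusive (ES analogously with ascending sorts). Selections are never empty
(minimum one element); `fraction = 0` is the documented degenerate case that
returns the raw areas. Two pooling variants exist because the scheme can be
read as "average all selected areas" or "average the three parts' means";
the pooled reading is the default and `"three_part"` is a config switch. The
global top-10% pool deliberately spans the whole video rather than a
neighbourhood of the ED — with heterogeneous per-cycle EFs this shrinks
per-cycle contrast slightly, which is the price of its robustness to
outliers.

The refinement's value is quantified in the acceptance suite: over 100
irregular-rhythm curves with one ED frame corrupted by a factor 0.7, the
pooled estimate's mean absolute error is an order of magnitude below the raw
peak's. A 90th/10th-percentile baseline (`baseline_percentile()`) is kept
for ablation; percentiles interpolate linearly between order statistics
(R's default type-7 convention, fixed so tests are exact).

## LV length

The length model is a voting ensemble over four base learners — extremely
randomised trees, AdaBoost.R2 over depth-3 regression trees, the lasso, and
a stack of ridge + 5-NN + gradient-boosted trees whose ridge meta-learner is
fitted on internal 5-fold out-of-fold predictions — combined by an
unweighted mean. Features per mask: pixel area, the extent along the
principal axis of the foreground pixels' second moments ("height"), and the
perpendicular widths at 10/30/50/70/90% of that height. The five-level width
profile is this package's concrete realisation of the loosely specified
"widths and heights" feature sketch; the principal axis is used rather than
apex detection because the axis only feeds features, not anatomy.

Defaults (all in `ensemble_spec()`): 100 trees/rounds, KNN $k = 5$,
regularisation 1.0, unweighted voting. These are ordinary textbook settings,
declared rather than tuned. On simulator-derived features with 1 px of
target noise the ensemble reaches held-out $R^2 \approx 0.99$; the
acceptance threshold is 0.9 on 500 rows. `compare_models()` evaluates
several specs on one seeded fold partition and runs a one-way ANOVA across
the per-fold $R^2$ groups (classical $F$ test; a zero within-group mean
square reports $F = \infty$, $p = 0$, capped rather than NaN).

At inference the pipeline predicts one length per phase (the ED frame's mask
and the ES frame's mask give different features), since EDV and ESV need
different lengths. When a human trace with an explicit long-axis chord is
available, the measured length can override the model
(`length_source = "trace"`); `length_source = "height"` uses the mask's
principal-axis extent directly and is exact for synthetic ellipses.

## Segmentation network

The segmenter follows the atrous-convolution family: a residual encoder
whose later stage replaces stride with dilation (rate 2), then atrous
spatial pyramid pooling — a 1×1 branch, three dilated 3×3 branches at rates
2/4/8, and a global-average-pooling branch, concatenated and projected —
followed by a 1×1 head, bilinear upsampling to input resolution and a
sigmoid. Total encoder stride is 4, so input sides must be divisible by 4.

Channel widths scale by a single config factor: `width_scale = 1` is the
full model (~3.4 M parameters), `1/8` (~53 k parameters) is the desk-scale
setting used in tests and trains in about a minute per 200 epochs on one
CPU. The loss is pixel-wise binary cross-entropy (computed in the
numerically safe log1p form) and the optimiser is Adam at learning rate
3e-3 with no augmentation; weight initialisation, batch shuffling and hence
the entire training run are deterministic given the config seed. The
backward pass is hand-derived and verified against central finite
differences in the development checks; the convolution kernels are im2col +
BLAS GEMM in C++.

The training fixture deliberately *overfits*: 10 frames of one synthetic
video, 200 epochs, mean Dice ≥ 0.95 against the generating masks
(observed ≈ 0.997). This validates that the architecture, gradients and
optimiser can fit the mapping; generalisation claims would need clinical
data and full-scale training, which are out of scope here. The Dice
coefficient is defined as $2|A \cap B| / (|A| + |B|)$ with the empty/empty
case set to 1 by convention.

## Evaluation statistics

`pearson_r()` and `paired_t()` wrap the classical exact-distribution tests;
`roc_auc()` computes the Mann–Whitney AUC (ties count ½) with the curve at
every distinct threshold, cross-checked in the tests against brute-force
pairwise enumeration for $n \le 50$; `bootstrap_ci()` is the basic
percentile bootstrap (default 100 resamples, 95% interval), resampling
subjects rather than frames, with failed resamples redrawn at most 10 times;
`confusion()` counts HFrEF flag agreement. All resampling is seeded through
`with_seed()`, which restores the caller's RNG state.

## Problem sizes and numerical choices

The shipped checks use: 112×112 rasters with ED axes around (80, 40) px
(ES short axis stays ≥ 20 px, where pixel-count areas agree with analytic
areas to 2%); 1–6 cycles with periods of 40–80 frames; 100 curves for the
corruption experiment; 200 simulated videos with 4% multiplicative area
noise for the all-cycle versus first-cycle comparison; 500 feature rows for
the length model; and the 10-frame/200-epoch overfit run. These sizes were
chosen so the whole suite completes in a few minutes while every comparison
retains a comfortable margin.

Degenerate inputs are handled explicitly rather than by exception where the
situation is expected in practice: constant area curves (no cycles), empty
masks (feature extraction refuses; the pipeline never reaches it because a
constant curve already short-circuits), multi-component masks (largest
component, with a warning), refined `a_ed <= a_es` (an error naming the
cycle, since a negative EF indicates an upstream failure), and 8-bit TIFF
round-trips (quantisation bounded by 1/255).

## Known limitations

- Clinical accuracy claims (correlation with expert EF, HFrEF AUC on real
  datasets) require the corresponding data and trained weights and are not
  reproduced here; readers for the annotation formats are provided so users
  with the data can run the identical pipeline.
- Only single-plane area-length volumes: no Simpson's biplane, no mL
  calibration, no strain or regurgitation analysis.
- Video ingestion is TIFF-stack based; compressed containers need external
  conversion because no codec library is bundled.
- The AF-like rhythm model varies cycle *length* only; it does not model
  beat-to-beat contractility coupling (e.g. post-pause potentiation) beyond
  the user-supplied per-cycle EF targets.
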