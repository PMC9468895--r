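---
title: "Staging early endometrial cancer by the tumor-to-uterus area ratio: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging early endometrial cancer by the tumor-to-uterus area ratio: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The staging problem and the TUR model

FIGO stage IA versus IB in early endometrial cancer is defined by the depth
of myometrial invasion (under versus at least half of the uterine muscle
wall). On a well-chosen 2-D MRI slice, deeper invasion shows up as a larger
tumor footprint relative to the organ, which motivates a single scalar
proxy: the tumor-to-uterus area ratio

$$\mathrm{TUR} = \frac{n_\text{tumor}}{n_\text{tumor} + n_\text{uterus}},$$

a pixel-count ratio on one slice, hence independent of voxel size and
acquisition scaling. Staging is a threshold rule — call IB when
$\mathrm{TUR} \ge c$ — with the criterion $c$ chosen per MRI sequence by
maximizing Youden's $J = \text{sensitivity} + \text{specificity} - 1$ along
the empirical ROC. IB is the positive class because its mean TUR exceeds
IA's on every sequence. Ties in $J$ resolve to the smallest threshold, and
scores exactly at the criterion are called IB; both conventions are fixed
here so results are bit-reproducible.

The per-sequence decisions can be fused. Because published summaries of
multi-sequence fusion are ambiguous about which class the votes reference,
`fusion_rule()` exposes a fully parameterized k-of-n rule (IB when at least
k of n sequence votes are IB) rather than hard-coding any one reading.

## The two-Gaussian TUR model as simulation oracle

Treating stage-conditional TURs as
$N(\mu_{IA},\sigma_{IA}^2)$ and $N(\mu_{IB},\sigma_{IB}^2)$ gives the
closed-form separability
$\mathrm{AUC} = \Phi\!\big((\mu_{IB}-\mu_{IA})/\sqrt{\sigma_{IA}^2+\sigma_{IB}^2}\big)$,
implemented as `gaussian_auc()`. With the clinically reported sagittal-T2WI
moments (0.103 ± 0.077 IA, 0.334 ± 0.125 IB) this evaluates to 0.942,
which is what large simulated cohorts reproduce empirically; the analytic
value anchors the stochastic tests.

## The phantom generator

`sample_cohort()` emulates exactly the features downstream code consumes,
and no more:

* one simply connected uterus per slice — a randomized filled ellipse
  covering 5–50% of the image (centre jitter ±8%, random orientation);
* one connected tumor strictly inside it, grown by seeded random annexation
  of the 4-connected frontier from an interior seed pixel. Growth stops
  when the tumor pixel count matches the intended TUR, so the realized TUR
  is exact up to rounding (±0.5/organ-area ≤ 0.01 at all permitted sizes).
  Random frontier subsets give the irregular, non-elliptical shapes that
  make tumors genuinely harder to segment than the organ;
* intended TURs drawn from the stage- and sequence-specific normals above,
  rejection-truncated to (0.02, 0.95). Rejection keeps the moments nearly
  intact (the truncated mass is small at these parameters) while
  guaranteeing a renderable tumor;
* three-level contrast per sequence (background/uterus/tumor mean
  intensities on the 8-bit scale: 60/115/175 axial T2WI, 35/90/210 axial
  DWI — tumor brightest under diffusion weighting — 70/125/185 sagittal
  T2WI), additive Gaussian noise (default SD 8), and an optional bright
  distractor blob outside the uterus labelled background, mimicking pelvic
  effusion, the documented false-positive mode of intensity-driven
  segmenters. Distractors are off by default;
* default image size 128 px (64 px in the desk-scale experiments below);
  clinical 256/512 inputs are configuration, not code.

What the phantom does **not** emulate: surrounding pelvic anatomy, partial
volume and bias fields, acquisition physics, multi-slice geometry, or
inter-annotator variability. Passing tests on phantoms therefore
demonstrate that the pipeline's machinery is correct and well calibrated —
not that the network would reach clinical Dice scores on patient images.

## Segmentation network

A standard U-net, desk-scaled: per resolution level two 3×3 convolutions
with ReLU, 2×2 max-pool, channels doubling; the decoder mirrors it with
nearest-neighbour upsampling, a 2×2 up-convolution halving channels, skip
concatenation and two 3×3 convolutions; a final 1×1 convolution yields
three class scores. Convolutions are same-padded rather than unpadded: the
output then aligns with the input with no crop bookkeeping, which is the
behaviour the full-size prediction overlays imply anyway; this is a
deliberate, documented deviation from the classic unpadded formulation.
Defaults are depth 4, 16 base channels and 128×128 inputs; the scaled-down
experiments use depth 3, 8 base channels at 64×64.

Training minimizes unweighted pixel-wise 3-class cross-entropy with Adam
(default learning rate 3e-4, the clinically reported setting; the
desk-scale experiments use 1e-3, which converges in far fewer epochs at
these image sizes), at most 300 epochs with early stopping (default
patience 20) and returns the best-validation-loss weights. Per-class loss
weights and horizontal-flip augmentation exist behind flags but are off by
default. One model per sequence is the default (per-sequence Dice is the
reported quantity clinically); a joint model is a switch, since the
original work does not state which was used. All randomness — He-normal
initialization, shuffling, augmentation — derives from one config seed.

Prediction is per-pixel argmax with ties broken toward the lower class
index, so an all-zero network yields all background. Arbitrary input sizes
are handled by the documented caller-side policy: bilinear resize for
intensities, nearest-neighbour for masks.

## Evaluation conventions

Dice uses whole-organ uterus membership by default: reference masks paint
the tumor inside the uterine outline, so the organ contour encloses both
labels and organ Dice is only well defined if tumor pixels count as uterus.
A strict uterus-label-only mode exists. When both sets are empty the Dice
is defined as 1 (perfect agreement); empty-reference/non-empty-prediction
gives 0. Group summaries report mean, sample SD (n−1; zero for n = 1) and
median. Two-sample comparisons default to the Welch t-test — the safer
choice when only "t-test" is specified — with Student and paired forms
available.

`compute_tur()` raises on a mask with no organ pixels rather than returning
0: an empty segmentation is a model failure that must surface, not a
stage-IA vote. The empirical ROC is evaluated at every distinct score; its
trapezoid area equals the Mann–Whitney statistic with ties counted ½, a
property the tests verify against a brute-force all-pairs count.

## Pipeline and reproducibility

`run_pipeline()` executes phantom → split → train → segment → DSC → TUR →
ROC → staging. The patient-level 6:1:3 split uses largest-remainder
apportionment (117 patients yield 70/12/35). Predictions, Dice and TUR are
produced for the whole cohort; ROC criteria are selected on the test
partition — mirroring the clinical analysis, which derived its thresholds
from held-out patients — and the staging report covers every patient with
its partition recorded. Stage seeds derive from one master seed by a fixed
Lehmer scheme (`derive_seed()`), so any stage can be re-run in isolation
and two runs with one master seed are byte-identical, which the tests check
on the emitted CSVs. A failing stage aborts with the stage name, leaving
partial artifacts and the run record on disk.

## Problem sizes used in the shipped experiments

Chosen as the smallest sizes at which each claim is meaningfully testable:
simulated ROC targets use 10,000 draws per stage (AUC standard error
≈ 0.003); generator calibration uses 504 rendered slices and 20,000-draw
cohorts; the segmentation analog trains one depth-3 net per sequence on a
40-patient, 64×64 cohort (24 train / 4 validation / 12 test patients, up to
80 epochs, patience 12, learning rate 1e-3) and evaluates held-out Dice;
pipeline smoke and determinism runs use 12 patients at 32×32. Phantom
classes are intensity-separable, so these desk-scale networks reach
high Dice quickly; the uterus-above-tumor Dice ordering observed clinically
reproduces because irregular tumor boundaries cost proportionally more
Dice at small sizes.

## Known limitations

* The phantom's intensity model makes segmentation easier than clinical
  MRI; Dice levels here are upper bounds on realism, though the
  ordering (uterus > tumor) and the TUR calibration transfer.
* Single-slice patients only; multi-slice selection is out of scope.
* Thresholds selected and evaluated on the same test partition reproduce
  the published workflow but overstate generalization; pass a disjoint
  cohort's TUR table to `roc_curve()`/`stage_cohort()` to avoid this.
* The CPU U-net is deliberately compact; clinical-scale 512×512 training is
  configurable but slow without hardware acceleration.
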