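# turstage

Automatic FIGO IA/IB staging of early endometrial cancer from 2-D pelvic
MRI slices, built around one interpretable imaging biomarker: the
**tumor-to-uterus area ratio (TUR)**.

Early endometrial cancer is staged by how deep the tumor invades the
myometrium — under 50% (stage IA) versus 50% or more (stage IB) — and the
two stages call for different surgery. Radiologist reads of preoperative
MRI are experience-dependent, so an automatic pipeline helps: segment the
uterus and the tumor on a slice, take the pixel-count ratio

```
TUR = |tumor| / (|tumor| + |uterus|)
```

and call stage IB when the TUR exceeds a per-sequence threshold selected by
ROC analysis (Youden's J = sensitivity + specificity − 1). Decisions from
the three routine sequences (axial T2WI, axial DWI, sagittal T2WI) can be
fused by a k-of-n vote.

The package implements the full workflow end to end:

* **Phantom generator** — synthetic pelvic slices (randomized elliptical
  uterus, irregular grown tumor, sequence-dependent contrast, noise, an
  optional bright "pelvic effusion" distractor) whose stage-conditional TUR
  distributions match the clinically reported per-sequence means and SDs,
  so every downstream stage is testable without patient data.
* **Annotation ingestion** — LabelMe-style polygon JSON to label masks
  (0 = background, 1 = uterus, 2 = tumor), plus the patient-level 6:1:3
  train/validation/test split.
* **Segmentation** — a compact, CPU-trainable U-net (same-padded 3×3
  conv + ReLU blocks, 2×2 max-pool encoder, upsample + 2×2 up-conv decoder
  with skip concatenation, 1×1 conv to 3 classes) trained with Adam on
  pixel-wise cross-entropy with early stopping. The convolution kernels and
  exact backprop are implemented in RcppArmadillo.
* **Evaluation** — Dice similarity coefficient `DSC = 2|X∩Y|/(|X|+|Y|)`
  per structure, cohort summaries, Welch t-tests.
* **Staging** — TUR, ROC/AUC (trapezoid ≡ Mann–Whitney with ties ½),
  Youden-optimal criterion, k-of-n fusion, accuracy/sensitivity/specificity.
* **Pipeline** — `run_pipeline()` wires phantom → split → train → segment →
  DSC → TUR → ROC → staging reproducibly from one master seed; a thin CLI
  lives at `inst/cli/turstage.R`.

## Worked example

```r
library(turstage)

# a 160-patient synthetic cohort (100 IA / 60 IB), one slice per sequence
coh <- sample_cohort(100, 60, default_phantom_params(64), seed = 7)

# TUR of the ground-truth masks, sagittal sequence
tur <- vapply(coh, function(cs) compute_tur(cs$slices$sagittal_t2w$mask), 0)
stage <- vapply(coh, `[[`, "", "stage")

roc <- roc_curve(tur, stage)
round(c(auc = roc$auc, criterion = roc$criterion,
        sens = roc$sens_at_criterion, spec = roc$spec_at_criterion), 3)
#>       auc criterion      sens      spec
#>     0.956     0.222     0.850     0.950
```

The empirical AUC sits by construction near the closed form
`gaussian_auc(0.103, 0.077, 0.334, 0.125)` = 0.942 for the sagittal
stage-conditional TUR distributions (sampling noise at n = 160 accounts for
the difference), and the Youden criterion of 0.22 falls between the IA
(≈ 0.10) and IB (≈ 0.33) mean TURs. A full synthetic
study — training the U-net per sequence and staging a held-out cohort — is
one call:

```r
run_pipeline(validate_config(list(n_ia = 20, n_ib = 12, image_size = 64,
                                  depth = 3, base_channels = 8, seed = 1)),
             out_dir = "run1")
```

which writes the cohort, split, model checkpoints, predicted masks,
`dsc.csv`, `tur.csv`, per-sequence ROC summaries and the fused
`staging_report.csv` under `run1/`.

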