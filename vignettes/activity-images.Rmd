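---
title: "Activity-image classification of upper-limb movements: methods notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-image classification of upper-limb movements: methods notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actimage)
```

This vignette documents the modelling choices behind the package: the
encoding and classifier, what the synthetic generator does and does not
emulate, the numerical conventions, and the decisions taken where the
design was genuinely open.

## The model

One recording is a single lift-and-lower movement of one upper limb,
captured as 3D positions (mm) of four markers — FN (finger nail, hand),
LEP (lateral epicondyle, forearm), MPH (mid-humerus, arm), ACR (acromion,
shoulder) — at 100 Hz. The pipeline maps it to a fixed-size tensor:

1. **Movement clipping.** Rest periods before and after the movement carry
   no class information and would dominate the resampled window. Onset and
   offset are detected on the hand marker's smoothed 3D speed.
2. **Side unification.** Left-limb movements are reflected across the
   lateral axis so a single model sees one canonical (right) side. The
   displacement feature uses absolute differences, so the reflection is
   exactly invisible downstream — mirror pairs encode to identical images
   (a property the tests verify over 100 random recordings).
3. **Resampling** of every axis to 32 samples by linear interpolation,
   removing duration as a trivial discriminator of image *size* (duration
   still shows up in the derivative magnitudes through the effective
   sampling interval, see below).
4. **Features.** Per axis: displacement $d_i = |p_i - p_{i-1}|$, then the
   chained first differences $v = \Delta d / T'$, $a = \Delta v / T'$,
   $j = \Delta a / T'$. Note these are derivatives of the *absolute
   displacement* series — implemented exactly as the chained formulas are
   written, not as derivatives of signed position. Four features × three
   axes gives 12 rows; each row is min–max normalized to $[0,1]$.
5. **Image assembly.** One 12 × 32 block per marker, stacked as channels:
   depth 1 (single marker) up to 4 ("RGBA" analogue).

The classifier is a fixed convolutional stack — conv 3×3 valid ($f_1$
filters, ReLU) → max-pool 2×2 → conv 3×3 valid ($f_2$, ReLU) → max-pool
2×2 → flatten → dense ($out_{Dense1}$, ReLU) → dropout ($d_{Drop1}$) →
dense softmax — trained with Adam (learning rate $lr$, $ep$ epochs,
mini-batch 32) on multi-class cross-entropy. On a 32 × 12 input the
spatial trace is 30×10 → 15×5 → 13×3 → 6×1, so the flattened width is
$6 f_2$. The network is small enough that a plain base-R implementation
(im2col + BLAS matrix products) trains the full 324-recording cohort for
100 epochs in well under a minute; backpropagation is verified against
numerical gradients in the test suite.

Two labelings are analysed: **limb3** (HUL healthy / NPUL non-paretic /
PUL paretic upper limb) and **group2** (G1 stroke / G2 control, both limbs
of stroke participants in G1). Classes are imbalanced by construction
(114/105/105 and 210/114 for the default cohort), so AUC is the headline
metric: binary ROC AUC for group2 and macro-averaged one-vs-rest AUC for
limb3 (the averaging scheme had to be chosen; macro is standard and
insensitive to imbalance). Precision and recall are macro averages for the
same reason.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `speed_fraction` | 0.05 | fraction of peak speed | standard kinematic onset convention |
| `min_hold` | 0.1 | s | rejects threshold crossings from noise |
| `backtrack_fraction` | 0.01 | fraction of peak | see "Onset detection" below |
| `n_samples` | 32 | samples | image width |
| `lr` | 1e-3 (search: 1e-5–1e-2, log) | – | Adam default scale |
| `ep` | 100 (search: 100–300) | epochs | enough to converge on 260 images |
| `f_conv1`, `f_conv2` | 32 (search: 10–100) | filters | small images need few filters |
| `d_drop1` | 0.2 (search: 0–0.25) | rate | single regularizer of the stack |
| `out_dense1` | 64 (search: 10–100) | units | |
| `batch_size` | 32 | samples | unspecified upstream; common default |

The hyperparameter search bounds are the tightest hyper-rectangle
containing every optimum reported in the reference experiments, so any of
those optima is reachable.

## The synthetic generator: a stated world

The clinical recordings are not redistributable, so every downstream stage
is exercised on a synthetic cohort whose structure matches the study: 35
stroke (G1) + 19 control (G2) participants × 2 limbs × 3 activities (DG,
SC, LC) = 324 recordings; each stroke participant has one pseudo-randomly
assigned paretic side.

A healthy lift is modelled as a minimum-jerk segment (amplitude set by the
activity: the glass rises ~250 mm to mouth level, cylinders ~380–400 mm to
head height, plus anterior reach and a small lateral drift), a 0.2 s hold,
and a minimum-jerk lowering; proximal markers follow amplitude-scaled
copies (FN 1.0 > LEP 0.55 > MPH 0.30 > ACR 0.12). Impairment is a
`class_effect` with five knobs, mapped onto the deficits reported for
post-stroke reaching:

- `duration_factor` (≥ 1): multiplies movement time — *longer movement
  time*;
- `peak_velocity_factor` (≤ 1): blends the minimum-jerk profile with a
  C²-smoothed trapezoid of the same amplitude and duration, lowering peak
  speed from $1.875A/D$ toward $1.25A/D$ — *lower peak velocity*,
  decoupled from duration;
- `n_submovements` (≥ 1): splits the lift into overlapping sub-profiles;
  minimum jerk is the unique jerk-cost minimizer, so any segmentation
  strictly raises the finite-difference jerk cost — *decreased smoothness*;
- `tremor_amplitude` (mm RMS): 4–10 Hz band-limited noise modulated by the
  instantaneous speed envelope (action tremor), so rest periods stay quiet
  and onset detection remains well-posed;
- `proximal_compensation` (≥ 0): extra displacement fraction for MPH and
  ACR — *greater proximal involvement*.

Defaults: paretic {1.5, 0.6, 3, 1.5 mm, 0.3}, non-paretic (milder,
bilateral involvement) {1.15, 0.85, 2, 0.5 mm, 0.1}, control null. The
magnitudes are not calibrated to clinical data — none are published — and
were chosen once so that the 2-class task is easy and the 3-class task
harder, mirroring the relative difficulty reported upstream; they were not
revisited after seeing test results. Per-recording duration (±10 %) and
amplitude (±5 %) jitter plus 0.5–1.0 s rest padding at each end make
recordings individually distinct and clipping non-trivial. An effect can
be restricted to a subset of markers (`markers =`), which provides ground
truth for the marker-sensitivity experiment.

**What a green test establishes — and what it does not.** The generator
produces smooth, noise-controlled, single-movement recordings with a known
class mechanism. A passing recovery test shows the pipeline can extract a
class signal of this kind; it says nothing about effect sizes, marker
dropout, soft-tissue artefacts, inter-trial variability structure, or any
other property of real clinical data. Accuracy numbers on synthetic
cohorts are pipeline checks, not clinical results.

## Numerical choices

- **Coordinates and units:** x lateral (right positive), y vertical, z
  anterior; millimetres; T = 0.01 s. Mirroring negates x.
- **Onset detection** is only ever described graphically upstream, so the
  rule is ours: 5-sample centred moving-average speed of FN, threshold 5 %
  of peak sustained for 0.1 s, then backtracking to 1 % of peak. Without
  backtracking the 5 % crossing of a minimum-jerk profile lies ~7 samples
  after the true onset, which would violate the package's own ±5-sample
  recovery property; backtracking is the standard refinement. One temporal
  window per recording (not per plane): independent per-plane windows
  would desynchronize the three axes that the image stacks as rows.
- **Length reconciliation:** the chained features yield 31/30/29/28
  samples from 32 positions, yet the image width is fixed at 32. Each
  series is left-padded by repeating its first value, preserving the
  temporal alignment of late samples. This is the largest interpretive gap
  in the encoding; right-padding or interpolation back to 32 would be
  defensible alternatives.
- **Effective interval:** derivatives after resampling use
  $T' = \textrm{clipped duration}/(32-1)$ rather than the raw T, so
  velocity magnitudes keep their physical scale across movements of
  different durations — a slow movement has genuinely smaller v/a/j values,
  which is part of the class signal.
- **Normalization scope:** per row, per recording (each feature of each
  marker on its own min/max), consistent with per-image visual encodings;
  a constant row maps to zeros. A side effect worth knowing: per-recording
  normalization removes absolute scale differences *between* recordings.
- **Convolution padding:** valid (unpadded); it yields the documented
  6×1 pre-flatten map.
- **Splits:** stratified by class at recording level by default;
  `group_by = "participant"` assigns whole participants to one side
  (stratified by their group) and is used for every headline number here,
  because recording-level splits leak participant identity — with three
  near-identical activities per limb, a recording-level split can place
  two recordings of the same limb on opposite sides.
- **Hyperparameter search:** GP with squared-exponential kernel on the
  unit cube (learning rate on a log scale), lengthscale and noise refit by
  marginal likelihood each call, expected-improvement acquisition over a
  random candidate set plus local perturbations of the incumbent, 10
  random initial points by default, and call-indexed training seeds so the
  whole run is reproducible. Whether the reference's 40 calls included its
  initial design is unknown; here `n_calls` counts every objective
  evaluation, including the initial ones.
- **Determinism:** all randomness flows from user seeds through R's RNG;
  training is deterministic given a seed and a fixed BLAS thread count.

## Limitations

- The CNN, random forest, linear SVM and GP optimizer are purpose-built
  base-R implementations (no deep-learning or forest library is available
  in the target environment). They are adequate for 12 × 32 images and
  cohorts of a few hundred recordings, not general-purpose tools.
- The logistic-regression baseline is ridge-regularized
  (`glmnet`, $\lambda = 1/n$) as a stand-in for the common C = 1 default
  of other ecosystems; coefficients are not identical to an unpenalized
  fit.
- The generator does not model joint constraints, inverse kinematics,
  trunk markers, marker occlusion or gap filling; recordings with missing
  samples are rejected at I/O.
- Reported headline results from the original clinical dataset are not
  reproducible from this package because that dataset is not included;
  all quantitative tests run on the synthetic world described above.
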