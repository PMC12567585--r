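---
title: "Multimodal ADHD screening from wrist accelerometry and clinical profiles"
author: "actimodal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal ADHD screening from wrist accelerometry and clinical profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Children with ADHD tend to move differently from typically developing
children in free-living conditions: more overall activity, but above all
burstier, more fragmented bouts with difficulty sustaining stillness.
Summary statistics of accelerometry (mean intensity, time in moderate
activity) discard exactly this temporal structure. `actimodal` implements a
pipeline that keeps it:

1. **ENMO.** Triaxial wrist acceleration $(x_t, y_t, z_t)$ in g at 100 Hz is
   reduced to $\mathrm{ENMO}_t = \sqrt{x_t^2+y_t^2+z_t^2} - 1$, removing the
   static gravity component.
2. **Gramian Angular Field (GAF).** Each analysis window is min–max
   normalised to $[-1,1]$, mapped to polar angles
   $\theta_t = \arccos \tilde v_t$ with time radius $r_t = t/T$, and encoded
   as the Gramian $G_{ij} = \cos(\theta_i + \theta_j)$, finally rescaled to
   $[0,1]$ pixel values. The field is symmetric and order-sensitive: two
   windows with equal cumulative activity but different temporal patterning
   produce different images.
3. **ViT–BiLSTM encoder.** Five consecutive window images form one model
   input. A Vision Transformer (classification head removed) embeds each
   frame as the final-layer class token; a two-layer bidirectional LSTM
   aggregates the five embeddings into per-frame tokens (dimension
   $2\times$hidden) and a pooled sequence vector.
4. **Cross-attention fusion.** The standardised clinical vector is
   projected to a query $Q$; the frame tokens supply keys and values. The
   fused representation is $\mathrm{softmax}(QK^\top/\sqrt{d_h})\,V$,
   followed by dropout and a softmax classifier over
   {ADHD, non-ADHD}. Three baseline fusions (concatenation, learnable
   weighted sum, dual-stream averaging) are provided for comparison.
5. **Labels.** SNAP-IV totals (26 items, 0–3) are cohort-standardised,
   $T = 10Z + 50$, and a child is labelled positive iff $T \ge 55$
   (boundary inclusive).

Training minimises focal loss
$-w_y (1-p_y)^\gamma \log p_y$ with inverse-frequency class weights and
$\gamma = 2$, using AdamW at a constant learning rate.

## Design choices where the protocol is open

Several details are not fixed by the screening protocol the package
implements; the choices below are the package's own and are all exposed in
configuration.

**Windowing.** The protocol does not state how continuous recordings map to
images. Default: 10 s non-overlapping windows of ENMO at 100 Hz (1000
samples), PAA-reduced to the image side length, five consecutive windows
per model input. PAA uses equal-measure bins with fractional boundaries
weighted by overlap, so the window mean is preserved exactly.

**Three channels.** GAF of a scalar ENMO signal yields one channel; the
model input is 3-channel. Default replicates the ENMO channel three times
(the literal reading, and compatible with 3-channel pretrained backbones);
a `per_axis` mode builds one GAF per raw axis instead.

**Normalisation scope.** The min–max of step 2 is computed per window, not
per recording, so each image uses its full dynamic range; the $[0,1]$
rescale is the fixed affine $(G+1)/2$ rather than per-image min–max, so
pixel values are comparable across images and exactly invertible.

**ENMO clipping.** Negative ENMO values are kept by default (the formula
taken literally); `clip_negative = TRUE` applies the common truncation at
zero.

**Attention token set.** Written literally, the fusion attends over a
*single* image vector, which makes the softmax trivial (weight 1) and the
fusion collapse to the projected value. The default instead uses the five
per-frame BiLSTM outputs as the key/value set, so attention can
re-weight frames; `single_token = TRUE` reproduces the literal collapsed
form. The default uses 4 attention heads partitioning $d_k$; set
`heads = 1` for the single-head equation. Query/key/value projections
carry no bias terms.

**Feature set.** The clinical vector defaults to sex, age, BMI, grade,
health, diet, parental education and the three SNAP-IV subscale scores.
The SNAP-IV *total* is excluded because the label is a deterministic
threshold on it; note the subscales still sum to the total, so
questionnaire information about the label remains in the features — see
the null-model discussion below.

**Optimiser.** Only the learning rate and weight decay are part of the
protocol; the optimiser is AdamW (standard for transformer fine-tuning,
and both printed hyperparameters map directly), with no learning-rate
schedule. The cohort standard deviation in the $T$-score uses denominator
$n-1$ (configurable).

**Label timing.** $Z$/$T$ scores are computed on the full cohort *before*
splitting: the screening label is defined per participant, not per fold.
The no-leakage rule applies to feature standardisation, which always uses
training-fold statistics only.

**Granularity.** Splits and cross-validation are at subject level; metrics
are reported both per sequence and per subject (mean positive probability
over a subject's sequences).

## The synthetic cohort

No participant data ships with the package; a generator reproduces the
statistical structure the method assumes so the whole pipeline is testable
offline. Defaults emulate the study conditions: 50 children, 26%
prevalence (exactly 13 positives), 100 Hz recordings, ages 7–13
(mean ≈ 9.2), BMI ≈ 16.6 ± 2.7, 58% male, and socioeconomic ordinals drawn
from the published cohort composition.

Activity is a two-state (rest/active) Markov-switching process over unit
gravity: rest is wear noise plus a slow orientation wobble; active bouts
add zero-mean burst noise. For the positive class the switching rate *and*
the active-state variance are multiplied by $1+\text{effect\_size}$
(default 2) — burstier, more fragmented movement. SNAP-IV items are
discretised normals on $\{0,\dots,3\}$ with control mean 1.5 per item and a
positive-class shift of `snap_shift` (default 0.9). That shift was chosen
so that (a) control totals land near the published female mean (~39) and
cohort totals near the published overall mean (~43), and (b) the derived
$T \ge 55$ labels agree with the generator's latent classes for ≥ 90% of
subjects, so the pipeline can be exercised against derived labels exactly
as the protocol prescribes. Recordings default to 2 minutes per subject —
a desk-scale length that still yields two 5-frame sequences per child.

What the generator does **not** model: circadian structure, device
calibration error, non-wear, posture, or any biomechanical realism.
Passing tests on synthetic cohorts therefore demonstrate that the
implementation recovers planted class structure of the assumed kind; they
say nothing about clinical performance on real recordings.

**The null check.** With `effect_size = 0` and `snap_shift = 0` the
generator is class-blind. But the *derived* labels are still a threshold
on the questionnaire totals, and the subscales are features, so a
classifier can legitimately predict derived labels above chance even in
the null — that association is structural, not evidence of signal
recovery. The meaningful null question is whether the pipeline fabricates
association with the generator's *latent* classes; the null test therefore
scores held-out predictions against `true_class`, pooled over three seeds
because an AUC on a 15-subject test set is too coarse to sit reliably in a
narrow band.

## Numerical implementation

No deep-learning framework is available to R here, so the encoder, fusion
heads and trainer run on a small reverse-mode automatic differentiation
engine included in the package (tape of matrix nodes; fused hand-derived
backward rules for multi-head attention, cross-attention and focal loss).
Every backward rule is verified against central finite differences in the
test suite, and the whole stack is exercised end-to-end by a gradient
check through ViT, BiLSTM and fusion.

Numerical conventions worth knowing:

- Polar encoding clamps values within `1e-8` of $[-1,1]$ and rejects
  larger excursions; the focal loss clamps $p_y$ at `1e-9` before the log.
- Metrics with zero denominators (e.g. precision with no predicted
  positives) return 0 with a warning.
- AUC is the trapezoidal area with tied scores grouped, which equals the
  midrank Mann–Whitney statistic exactly.
- Split quotas use largest-remainder rounding per class (ties in set
  order train/val/test); k-fold dealing offsets the start fold between
  classes so overall fold sizes stay balanced.
- Constant windows (no dynamic range) are rejected rather than silently
  mapped; the generator's wear noise guarantees non-degenerate windows.
- Eval-mode forward passes are deterministic; training is reproducible
  given the seed (weights, shuffling and dropout masks all derive from
  it).

## Problem sizes used in tests

The tiny preset (32×32 images, patch 8, depth 2, embed 64; BiLSTM hidden
32; $d_k = 32$) with learning rate 1e-3 over 20 epochs is the package's
CPU-scale configuration: a full 50-subject fit takes well under a minute,
and the four-fusion comparison uses 3-fold cross-validation. The
full-size configuration (224×224, patch 16, depth 12, embed 768, hidden
128, $d_k = 128$) is exercised for its dimension contracts — per-frame
embedding 768, frame token 256, fused vector 128, two logits — and is the
configuration a GPU-scale study would train, with 55/15/30 subject-level
splits, batch 8, learning rate 1e-4, weight decay 1e-5, dropout 0.5 and
10-fold cross-validation.

## Known limitations

- Random-initialised tiny ViT: on desk-scale synthetic cohorts most of
  the recoverable signal lives in the questionnaire features, so the
  image branch's contribution is modest; demonstrating image-dominant
  recovery would need longer recordings and pretrained backbones.
- The three baseline fusion heads are reasonable reconstructions; their
  exact original architectures are not specified anywhere, so only their
  qualitative roles (late concatenation, gated sum, independent streams)
  are meaningful.
- `pretrained = TRUE` requires a user-supplied checkpoint; none ships
  with the package.
- No gravity-component filtering, calibration, or non-wear detection is
  applied before ENMO.
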