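# actimodal

Multimodal ADHD screening from wrist accelerometry and clinical
questionnaires, for researchers in wearable-sensor digital phenotyping of
paediatric behavioural health.

Children with ADHD tend to move in burstier, more fragmented bouts than
typically developing children. Tabular activity summaries (mean intensity,
time-in-zone) discard that temporal structure. `actimodal` keeps it by
re-encoding the signal as images and fusing them with clinical profiles:

- **ENMO**: triaxial acceleration (g, 100 Hz) reduced to
  `sqrt(x² + y² + z²) − 1`, removing static gravity;
- **GAF**: each analysis window is min–max normalised to [−1, 1], mapped
  to polar angles `θ_t = arccos(ṽ_t)`, and imaged as the Gramian
  `G[i,j] = cos(θ_i + θ_j)`, rescaled to [0, 1] — a symmetric,
  order-sensitive encoding of the window;
- **ViT–BiLSTM**: a Vision Transformer embeds each of 5 consecutive window
  images (final-layer class token); a 2-layer bidirectional LSTM
  aggregates them into per-frame tokens and a pooled vector;
- **Cross-attention fusion**: the standardised clinical vector is the
  query, frame tokens are keys/values:
  `F_fused = softmax(QKᵀ/√d_h) V`, then dropout and a 2-class softmax.
  Baselines: simple concatenation, learnable weighted sum, dual-stream;
- **Labels**: SNAP-IV totals (26 items, 0–3) are cohort-standardised,
  `T = 10Z + 50`; a child is ADHD-positive iff `T ≥ 55`;
- **Training**: focal loss `−w_y (1−p_y)^γ log p_y` with inverse-frequency
  class weights, AdamW, constant learning rate, subject-level stratified
  55/15/30 splits and stratified k-fold cross-validation;
- **Metrics**: accuracy, precision, recall, F1, trapezoidal ROC-AUC
  (equal to the midrank Mann–Whitney statistic), MCC.

A synthetic cohort generator reproduces the assumed statistical structure
(50 children, 26% prevalence, class-dependent movement dynamics and
questionnaire shifts), so the entire pipeline runs and is tested without
any participant data. The neural stack runs on a small reverse-mode
autodiff engine included in the package (no deep-learning framework
dependency); all gradients are verified against finite differences in the
test suite.

## Worked example

```r
library(actimodal)

# a synthetic 50-child cohort at the default study conditions
cohort <- generate_cohort(cohort_spec())

# end-to-end: labels, subject-level split, GAF encoding, training, test
fit <- fit_multimodal(cohort)   # tiny CPU preset, cross-attention fusion
fit$evaluation
#> <evaluation>
#>   sequence: accuracy 0.900  precision 0.778  recall 0.875  f1 0.824  auc 0.949  mcc 0.757
#>   subject:  accuracy 0.933  precision 0.800  recall 1.000  f1 0.889  auc 1.000  mcc 0.853
```

The `sequence` row scores every 5-frame image sequence independently; the
`subject` row averages each held-out child's sequence probabilities first,
so each child counts once — on this run the 15 test children are ranked
perfectly (AUC 1.0), with one false positive at the 0.5 threshold
(accuracy 0.933, precision 0.8).

Individual stages are exposed directly:

```r
enmo <- compute_enmo(cohort$subjects[[1]]$series)
seqs <- window_to_sequence(enmo, window_config(image_size = 32), "S001")
emb  <- vit_encode_frames(fit$model, seqs[[1]])       # 5 x 64 (tiny preset)
tok  <- bilstm_temporal(fit$model, emb)               # tokens + pooled
cross_attention_fuse(fit$model, rnorm(10), tok$tokens)$weights  # 4 x 5, rows sum to 1

cv <- cross_validate(cohort, k = 3)   # all four fusion strategies
print(cv)
```

A command-line front end (`simulate`, `encode`, `prep-clinical`, `train`,
`evaluate`, `crossval`, `run-all`) ships at
`system.file("cli", "actimodal.R", package = "actimodal")`.

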