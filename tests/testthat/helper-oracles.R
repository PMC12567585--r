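# Independent oracles, coded separately from the implementation paths they
# check.

# Algebraic form of the Gramian angular field: for v in [-1, 1],
# cos(theta_i + theta_j) = v_i v_j - sqrt(1 - v_i^2) sqrt(1 - v_j^2).
gaf_oracle <- function(v) {
  s <- sqrt(pmax(0, 1 - v^2))
  outer(v, v) - outer(s, s)
}

# Direct transcription of the confusion-matrix metric formulas.
metric_oracle <- function(TP, TN, FP, FN) {
  total <- TP + TN + FP + FN
  prec <- if (TP + FP > 0) TP / (TP + FP) else 0
  rec <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (den > 0) (TP * TN - FP * FN) / den else 0
  list(accuracy = (TP + TN) / total, precision = prec, recall = rec,
       f1 = f1, mcc = mcc)
}

# Mann-Whitney AUC via midranks: U / (n1 * n0).
auc_rank_oracle <- function(scores, labels) {
  r <- rank(scores)  # midranks on ties
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Fractional-bin PAA oracle: replicate each sample m times so the m equal
# bins align exactly with sample boundaries, then take plain bin means.
paa_oracle <- function(v, m) {
  up <- rep(v, each = m)            # length n * m, bins of exactly n
  colMeans(matrix(up, ncol = m))
}
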