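#' Evaluate a model on a sample set
#'
#' Reports the six-metric suite at two granularities: per sequence (every
#' image sequence scored independently) and per subject (the positive-class
#' probabilities of a subject's sequences are averaged before thresholding,
#' so each child contributes one prediction).
#'
#' @param model A trained `actimodal_model`.
#' @param samples Samples from [build_samples()].
#' @return Object of class `evaluation`: `sequence` and `subject` metric
#'   lists ([metrics_from_predictions()]), plus `predictions` and
#'   `subject_predictions` data frames.
#' @export
evaluate_model <- function(model, samples) {
  pred <- predict_model(model, samples)
  subj <- stats::aggregate(cbind(p_pos, label) ~ subject_id, data = pred, mean)
  subj$label <- as.integer(subj$label)  # constant within subject
  subj$pred <- as.integer(subj$p_pos >= 0.5)
  structure(list(sequence = metrics_from_predictions(pred$p_pos, pred$label),
                 subject = metrics_from_predictions(subj$p_pos, subj$label),
                 predictions = pred, subject_predictions = subj),
            class = "evaluation")
}

#' @export
print.evaluation <- function(x, ...) {
  fmt <- function(m) paste(sprintf("%s %.3f", names(m), unlist(m)),
                           collapse = "  ")
  cat("<evaluation>\n  sequence: ", fmt(x$sequence), "\n  subject:  ",
      fmt(x$subject), "\n", sep = "")
  invisible(x)
}

metric_names <- c("accuracy", "precision", "recall", "f1", "auc", "mcc")

#' End-to-end fit on a cohort
#'
#' Convenience wrapper running the full study protocol on one cohort:
#' label derivation ([build_cohort_table()]), stratified subject-level
#' split, training-fold feature standardisation, GAF sequence encoding,
#' model training and held-out test evaluation.
#'
#' @param cohort A `synthetic_cohort` (or compatible list with `subjects`
#'   and `clinical`).
#' @param windowing A [window_config()]; its `image_size` must match the
#'   model's ViT config.
#' @param fusion_kind Fusion strategy for the model.
#' @param cfg A [train_config()].
#' @param fractions Train/val/test fractions.
#' @param feature_cols Clinical feature columns.
#' @param model_cfg Optional [model_config()]; defaults to
#'   [tiny_model_config()] sized to the feature set.
#' @param seed Seed for the split and weight init (defaults to
#'   `cfg$seed`).
#' @return List: `model` (trained), `split`, `table` (cohort table),
#'   `standardiser`, `evaluation` (held-out test, see [evaluate_model()]),
#'   `sequences_per_set` counts.
#' @export
fit_multimodal <- function(cohort, windowing = window_config(image_size = 32),
                           fusion_kind = "cross_attention",
                           cfg = tiny_train_config(),
                           fractions = c(0.55, 0.15, 0.30),
                           feature_cols = clinical_feature_defaults(),
                           model_cfg = NULL, seed = cfg$seed) {
  table <- build_cohort_table(cohort$clinical)
  ids <- table$subject_id
  split <- subject_split(ids, table$label, fractions, seed = seed)
  std <- standardise_features(table, split$train, feature_cols)
  labels <- stats::setNames(table$label, ids)
  sequences <- encode_cohort(cohort, windowing)
  if (is.null(model_cfg))
    model_cfg <- tiny_model_config(ncol(std$features), fusion_kind)
  seq_of <- function(set) Filter(function(s) s$subject_id %in% set, sequences)
  mk <- function(set) build_samples(seq_of(set), std$features, labels,
                                    model_cfg$vit)
  tr <- mk(split$train)
  va <- if (length(split$val)) mk(split$val) else NULL
  te <- mk(split$test)
  model <- build_model(model_cfg, seed = seed)
  model <- train_model(model, tr, va, cfg)
  list(model = model, split = split, table = table, standardiser = std,
       evaluation = evaluate_model(model, te),
       sequences_per_set = c(train = length(tr), val = length(va),
                             test = length(te)))
}

#' Stratified k-fold cross-validation over fusion strategies
#'
#' For each requested fusion kind and each fold: subjects of the fold are
#' held out, features are re-standardised on the remaining subjects (no
#' leakage), a fresh model is trained for the full epoch budget, and the
#' held-out subjects are scored at subject level. A fold whose training
#' fails is recorded as failed and the run continues.
#'
#' @param cohort A `synthetic_cohort`.
#' @param windowing A [window_config()].
#' @param fusion_kinds Character vector of fusion strategies to compare.
#' @param k Number of folds (default 3 at desk scale; the full protocol
#'   value is 10).
#' @param cfg A [train_config()].
#' @param feature_cols Clinical feature columns.
#' @param seed Seed for fold assignment and weight init.
#' @return Object of class `cv_report`: `folds` (per-fold metric rows),
#'   `summary` (mean and sd per fusion kind and metric), `failed`
#'   (data.frame of failed folds, possibly empty).
#' @export
cross_validate <- function(cohort, windowing = window_config(image_size = 32),
                           fusion_kinds = c("cross_attention", "simple_concat",
                                            "weighted_sum", "dual_stream"),
                           k = 3, cfg = tiny_train_config(),
                           feature_cols = clinical_feature_defaults(),
                           seed = cfg$seed) {
  table <- build_cohort_table(cohort$clinical)
  ids <- table$subject_id
  labels <- stats::setNames(table$label, ids)
  folds <- stratified_kfold(ids, table$label, k = k, seed = seed)
  sequences <- encode_cohort(cohort, windowing)
  rows <- list()
  failed <- list()
  for (kind in fusion_kinds) {
    for (f in seq_len(k)) {
      test_ids <- names(folds)[folds == f]
      train_ids <- names(folds)[folds != f]
      res <- tryCatch({
        std <- standardise_features(table, train_ids, feature_cols)
        mcfg <- tiny_model_config(ncol(std$features), kind)
        mk <- function(set)
          build_samples(Filter(function(s) s$subject_id %in% set, sequences),
                        std$features, labels, mcfg$vit)
        model <- build_model(mcfg, seed = seed + f)
        model <- train_model(model, mk(train_ids), NULL, cfg)
        ev <- evaluate_model(model, mk(test_ids))
        as.data.frame(c(list(fusion = kind, fold = f), ev$subject))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("fold %d (%s) failed: %s", f, kind,
                        conditionMessage(res)))
        failed[[length(failed) + 1L]] <-
          data.frame(fusion = kind, fold = f, error = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  folds_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fusion = character(), fold = integer())
  summ <- NULL
  if (nrow(folds_df)) {
    agg <- function(fun, tag) {
      a <- stats::aggregate(folds_df[metric_names],
                            by = list(fusion = folds_df$fusion), fun)
      a$stat <- tag
      a
    }
    summ <- rbind(agg(mean, "mean"), agg(stats::sd, "sd"))
  }
  structure(list(folds = folds_df, summary = summ,
                 failed = if (length(failed)) do.call(rbind, failed) else
                   data.frame(),
                 k = k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat(sprintf("<cv_report> %d-fold stratified cross-validation\n", x$k))
  if (is.null(x$summary)) {
    cat("  (no successful folds)\n")
    return(invisible(x))
  }
  mn <- x$summary[x$summary$stat == "mean", ]
  sdv <- x$summary[x$summary$stat == "sd", ]
  for (i in seq_len(nrow(mn))) {
    j <- match(mn$fusion[i], sdv$fusion)
    cells <- sprintf("%.*f +/- %.*f", digits, unlist(mn[i, metric_names]),
                     digits, unlist(sdv[j, metric_names]))
    cat(sprintf("  %-16s %s\n", mn$fusion[i],
                paste(sprintf("%s %s", metric_names, cells), collapse = "  ")))
  }
  if (nrow(x$failed))
    cat(sprintf("  !! %d failed fold(s)\n", nrow(x$failed)))
  invisible(x)
}
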