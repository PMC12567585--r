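#' @title SNAP-IV scoring and ADHD labelling
#' @description Helpers for the 26-item Swanson, Nolan and Pelham (SNAP-IV)
#'   rating scale: items 1-9 inattention, 10-18 hyperactivity/impulsivity,
#'   19-26 oppositional defiance, each rated 0 (not at all) to 3 (very much).
#' @name snapiv
NULL

snap_blocks <- list(inattention = 1:9, hyperactivity = 10:18,
                    oppositional = 19:26)

#' Score a SNAP-IV response
#'
#' @param items Integer vector of exactly 26 ratings in `{0, 1, 2, 3}`,
#'   ordered inattention (1-9), hyperactivity/impulsivity (10-18),
#'   oppositional (19-26).
#' @return Object of class `snap_scores` with subscale sums `inattention`
#'   (0-27), `hyperactivity` (0-27), `oppositional` (0-24) and `total`
#'   (0-78, the sum of all 26 items).
#' @export
score_snapiv <- function(items) {
  if (length(items) != 26L)
    stop(sprintf("expected 26 SNAP-IV items, got %d", length(items)))
  bad <- which(!items %in% 0:3)
  if (length(bad))
    stop(sprintf("SNAP-IV item %d out of range 0..3 (value %s)",
                 bad[1], as.character(items[bad[1]])))
  items <- as.integer(items)
  structure(list(inattention = sum(items[snap_blocks$inattention]),
                 hyperactivity = sum(items[snap_blocks$hyperactivity]),
                 oppositional = sum(items[snap_blocks$oppositional]),
                 total = sum(items)),
            class = "snap_scores")
}

#' Cohort T-scores from SNAP-IV totals
#'
#' Standardises totals within the cohort, `Z = (total - mean) / sd`, then
#' rescales to the T metric, `T = 10 * Z + 50`. The cohort standard
#' deviation uses denominator `n - 1` by default (sample sd); a population
#' (`n`) denominator is available for compatibility.
#'
#' @param totals Numeric vector of per-subject SNAP-IV totals (length >= 2).
#' @param sd_denom `"n-1"` (default) or `"n"`.
#' @return Numeric vector of T-scores.
#' @export
t_score <- function(totals, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  n <- length(totals)
  if (n < 2L) stop("need at least 2 subjects for a cohort T-score")
  if (any(!is.finite(totals))) stop("non-finite totals")
  s <- stats::sd(totals)
  if (sd_denom == "n") s <- s * sqrt((n - 1) / n)
  if (!is.finite(s) || s == 0)
    stop("degenerate cohort: zero standard deviation of totals")
  10 * (totals - mean(totals)) / s + 50
}

#' Binary ADHD symptom labels from T-scores
#'
#' Labels a subject positive exactly when `T >= threshold`; the boundary
#' value itself is positive.
#'
#' @param t Numeric T-scores.
#' @param threshold Cut-off, default 55 (i.e. half a cohort standard
#'   deviation above the mean).
#' @return Integer vector of 0/1 labels.
#' @export
label_adhd <- function(t, threshold = 55) {
  if (any(!is.finite(t))) stop("non-finite T-score")
  as.integer(t >= threshold)
}

#' Impute missing values in a clinical table
#'
#' Numeric gaps are filled with the column mean, categorical/ordinal gaps
#' with the most frequent category (ties broken towards the lowest encoded
#' category, with a message). A fully missing column is an error.
#'
#' @param df A data.frame; missing values as `NA`.
#' @param categorical_cols Character vector naming the columns to treat as
#'   categorical (mode imputation). All other non-id columns are numeric.
#' @param id_col Identifier column, left untouched.
#' @return The completed data.frame (no `NA` remains in imputed columns).
#' @export
impute_missing <- function(df, categorical_cols = character(),
                           id_col = "subject_id") {
  for (col in setdiff(names(df), id_col)) {
    v <- df[[col]]
    miss <- is.na(v)
    if (!any(miss)) next
    if (all(miss)) stop(sprintf("column '%s' is fully missing", col))
    if (col %in% categorical_cols) {
      tab <- table(v[!miss])
      best <- names(tab)[tab == max(tab)]
      if (length(best) > 1L)
        message(sprintf("mode tie in '%s'; using lowest category", col))
      fill <- sort(best)[1]
      # preserve numeric encoding where the column is numeric
      if (is.numeric(v)) fill <- as.numeric(fill)
      v[miss] <- fill
    } else {
      v[miss] <- mean(v[!miss])
    }
    df[[col]] <- v
  }
  df
}

#' Default clinical feature columns
#'
#' The tabular feature vector entering the fusion model: demographics,
#' socioeconomic ordinals, and the three SNAP-IV subscale scores.
#'
#' The SNAP-IV *total* score is deliberately excluded: the ADHD label is a
#' deterministic threshold on the cohort-standardised total, so including it
#' would leak the label into the features. Note that the three subscales sum
#' to the total, so questionnaire-derived information about the label
#' remains present; drop the `snap_*` entries as well for a questionnaire-free
#' feature set.
#'
#' @return Character vector of column names.
#' @export
clinical_feature_defaults <- function() {
  c("sex", "age", "bmi", "grade", "health_state", "diet_state",
    "parental_education", "snap_inattention", "snap_hyperactivity",
    "snap_oppositional")
}

snap_item_cols <- function() sprintf("snap_%02d", 1:26)

#' Build the cohort table: scores, T-scores, labels
#'
#' Takes a raw per-subject clinical table (one row per subject with
#' demographic columns plus SNAP-IV item columns `snap_01` .. `snap_26`),
#' imputes missing values, scores the questionnaire, derives cohort
#' T-scores and binary ADHD labels. The label is defined on the full cohort
#' before any train/test splitting, mirroring how the screening protocol
#' assigns a label to every participant; feature standardisation (which must
#' not leak across splits) is a separate step, [standardise_features()].
#'
#' @param clinical A data.frame with columns `subject_id`, `sex`, `age`,
#'   `bmi`, `grade`, `health_state`, `diet_state`, `parental_education`,
#'   and `snap_01` .. `snap_26`.
#' @param sd_denom Passed to [t_score()].
#' @param threshold Passed to [label_adhd()].
#' @return Object of class `cohort_table`: the completed data.frame with
#'   added columns `snap_inattention`, `snap_hyperactivity`,
#'   `snap_oppositional`, `snap_total`, `t_score`, `label`.
#' @export
build_cohort_table <- function(clinical, sd_denom = "n-1", threshold = 55) {
  need <- c("subject_id", "sex", "age", "bmi", "grade", "health_state",
            "diet_state", "parental_education", snap_item_cols())
  missing_cols <- setdiff(need, names(clinical))
  if (length(missing_cols))
    stop("clinical table missing columns: ", paste(missing_cols, collapse = ", "))
  cat_cols <- c("sex", "grade", "health_state", "diet_state",
                "parental_education", snap_item_cols())
  df <- impute_missing(clinical, categorical_cols = cat_cols)
  items <- as.matrix(df[, snap_item_cols()])
  scores <- t(apply(items, 1L, function(r) {
    s <- score_snapiv(r)
    c(s$inattention, s$hyperactivity, s$oppositional, s$total)
  }))
  df$snap_inattention <- scores[, 1]
  df$snap_hyperactivity <- scores[, 2]
  df$snap_oppositional <- scores[, 3]
  df$snap_total <- scores[, 4]
  df$t_score <- t_score(df$snap_total, sd_denom = sd_denom)
  df$label <- label_adhd(df$t_score, threshold = threshold)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Standardise clinical features with training-fold statistics
#'
#' Centres and scales the selected feature columns using the mean and
#' standard deviation of the *training* subjects only, then applies those
#' statistics to every subject. Held-out rows therefore never influence the
#' stored statistics. A feature with zero variance in the training fold is
#' dropped with a warning.
#'
#' @param table A [build_cohort_table()] result (or plain data.frame).
#' @param train_ids Subject ids forming the training fold.
#' @param feature_cols Feature columns; default [clinical_feature_defaults()].
#' @param id_col Identifier column name.
#' @return List with `features` (matrix, rownames = subject ids, all
#'   subjects), `center`, `scale`, `columns` (the columns kept).
#' @export
standardise_features <- function(table, train_ids,
                                 feature_cols = clinical_feature_defaults(),
                                 id_col = "subject_id") {
  if (!length(train_ids)) stop("empty training subject set")
  miss <- setdiff(feature_cols, names(table))
  if (length(miss)) stop("unknown feature columns: ", paste(miss, collapse = ", "))
  tr <- table[[id_col]] %in% train_ids
  if (!any(tr)) stop("no rows match the training ids")
  X <- as.matrix(table[, feature_cols, drop = FALSE])
  storage.mode(X) <- "double"
  ctr <- colMeans(X[tr, , drop = FALSE])
  scl <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
  drop_cols <- which(!is.finite(scl) | scl == 0)
  if (length(drop_cols)) {
    warning("dropping zero-variance training feature(s): ",
            paste(feature_cols[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
    ctr <- ctr[-drop_cols]
    scl <- scl[-drop_cols]
    feature_cols <- feature_cols[-drop_cols]
  }
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  rownames(Z) <- as.character(table[[id_col]])
  list(features = Z, center = ctr, scale = scl, columns = feature_cols)
}
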