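#' Synthetic cohort specification
#'
#' Defines the study conditions emulated by the generator: a 50-child
#' cohort at 26% ADHD prevalence wearing a 100 Hz wrist accelerometer,
#' with class-dependent activity dynamics (the positive class moves in
#' burstier, more fragmented bouts) and SNAP-IV item responses whose totals
#' separate the classes.
#'
#' @param n_subjects Cohort size (default 50).
#' @param prevalence Fraction of positive (ADHD-class) subjects; the number
#'   of positives is `round(prevalence * n_subjects)` exactly (default 0.26,
#'   i.e. 13 of 50).
#' @param minutes_per_subject Recording length per subject (default 2; a
#'   desk-scale preset that still yields several image sequences per child).
#' @param rate_hz Sampling rate (default 100).
#' @param effect_size Separation of class activity dynamics; 0 is the null.
#'   The positive class has its bout-switching rate and its active-state
#'   burst variance multiplied by `1 + effect_size`.
#' @param snap_shift Upward shift of the positive class per-item mean score
#'   on the 0-3 scale (default 0.9; see the methods vignette for the
#'   calibration rationale).
#' @param seed Integer master seed; every subject draws from a substream
#'   keyed by `(seed, subject index)`.
#' @param enmo_cap Physical plausibility cap: samples are rescaled so the
#'   acceleration norm never exceeds `1 + enmo_cap` g (default 6).
#' @param missing_rate Fraction of demographic cells blanked to `NA`, to
#'   exercise imputation (default 0).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 50, prevalence = 0.26,
                        minutes_per_subject = 2, rate_hz = 100,
                        effect_size = 2, snap_shift = 0.9, seed = 42,
                        enmo_cap = 6, missing_rate = 0) {
  stopifnot(n_subjects >= 2, prevalence >= 0, prevalence <= 1,
            minutes_per_subject > 0, rate_hz > 0, effect_size >= 0,
            snap_shift >= 0, enmo_cap > 0,
            missing_rate >= 0, missing_rate < 1)
  n_pos <- as.integer(round(prevalence * n_subjects))
  structure(list(n_subjects = as.integer(n_subjects), prevalence = prevalence,
                 n_positive = n_pos,
                 minutes_per_subject = minutes_per_subject,
                 rate_hz = rate_hz, effect_size = effect_size,
                 snap_shift = snap_shift, seed = as.integer(seed),
                 enmo_cap = enmo_cap, missing_rate = missing_rate),
            class = "cohort_spec")
}

# Deterministic per-subject substream seed; stays below 2^31.
subject_seed <- function(seed, i, salt = 0L) {
  as.integer((as.numeric(seed %% 100003L) * 20011 + i * 7919 + salt * 104729) %%
               2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one subject's accelerometer signal
#'
#' Two-state (rest/active) Markov-switching model on top of unit gravity.
#' Rest is near-still wear noise; active bouts add zero-mean burst noise on
#' all three axes. For the positive class both the switching rate and the
#' active-state burst variance are multiplied by `1 + effect_size`,
#' producing the burstier, more fragmented movement that motivates
#' image-based encoding. With `effect_size = 0` the class-conditional
#' distributions are identical by construction.
#'
#' @param class 0 (control) or 1 (ADHD class).
#' @param spec A [cohort_spec()].
#' @param seed Substream seed for this subject.
#' @return A [triaxial_series()].
#' @export
generate_subject_signal <- function(class, spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"), class %in% 0:1)
  n <- as.integer(round(spec$minutes_per_subject * 60 * spec$rate_hz))
  boost <- 1 + if (class == 1L) spec$effect_size else 0
  rate_ra <- 0.08 * boost   # rest -> active switches per second
  rate_ar <- 0.25 * boost   # active -> rest
  sd_rest <- 0.015          # g, wear noise
  sd_active <- 0.2 * sqrt(boost)  # g per axis during bouts
  with_seed(seed, {
    # dwell-time simulation of the two-state chain, in samples
    state <- integer(n)
    pos <- 1L
    cur <- 0L  # start at rest
    while (pos <= n) {
      rate <- if (cur == 0L) rate_ra else rate_ar
      dwell <- max(1L, as.integer(round(stats::rexp(1, rate) * spec$rate_hz)))
      end <- min(n, pos + dwell - 1L)
      state[pos:end] <- cur
      pos <- end + 1L
      cur <- 1L - cur
    }
    sdv <- ifelse(state == 1L, sd_active, sd_rest)
    x <- stats::rnorm(n, 0, sdv)
    y <- stats::rnorm(n, 0, sdv)
    z <- 1 + stats::rnorm(n, 0, sdv)
    # slow orientation wobble so rest windows are not pure white noise
    t_sec <- (seq_len(n) - 1) / spec$rate_hz
    x <- x + 0.03 * sin(2 * pi * 0.05 * t_sec + stats::runif(1, 0, 2 * pi))
    y <- y + 0.03 * sin(2 * pi * 0.03 * t_sec + stats::runif(1, 0, 2 * pi))
    nrm <- sqrt(x^2 + y^2 + z^2)
    cap <- 1 + spec$enmo_cap
    over <- nrm > cap
    if (any(over)) {
      f <- cap / nrm[over]
      x[over] <- x[over] * f; y[over] <- y[over] * f; z[over] <- z[over] * f
    }
    triaxial_series(x, y, z, rate_hz = spec$rate_hz)
  })
}

#' Generate one subject's SNAP-IV response
#'
#' Each of the 26 items is an independent draw from a discretised normal on
#' `{0, 1, 2, 3}` (rounded and truncated). The control class has per-item
#' mean 1.5; the positive class is shifted upward by `spec$snap_shift`.
#' With `snap_shift = 0` the class-conditional distributions are identical.
#'
#' @inheritParams generate_subject_signal
#' @return Integer vector of 26 item scores.
#' @export
generate_snapiv <- function(class, spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"), class %in% 0:1)
  m <- 1.5 + if (class == 1L) spec$snap_shift else 0
  with_seed(seed, {
    as.integer(pmin(3, pmax(0, round(stats::rnorm(26, m, 0.8)))))
  })
}

# demographics loosely matching a 7-13 y school cohort
generate_demographics <- function(seed) {
  with_seed(seed, {
    age <- min(13L, max(7L, as.integer(round(stats::rnorm(1, 9.16, 1.68)))))
    list(sex = ifelse(stats::runif(1) < 0.58, 0L, 1L),  # male = 0, female = 1
         age = age,
         bmi = round(min(22.8, max(11.7, stats::rnorm(1, 16.57, 2.69))), 1),
         grade = min(7L, max(1L, age - 6L)),
         health_state = sample(1:3, 1, prob = c(0.14, 0.85, 0.01)),
         diet_state = sample(1:3, 1, prob = c(0.26, 0.70, 0.04)),
         parental_education = sample(1:3, 1, prob = c(0.16, 0.80, 0.04)))
  })
}

#' Generate a full synthetic cohort
#'
#' Draws exactly `round(prevalence * n_subjects)` positive subjects (their
#' positions chosen from the cohort-level stream), then generates each
#' subject's signal, questionnaire response and demographics from a
#' per-subject substream keyed by `(seed, subject index)`, so the whole
#' cohort is bit-reproducible from the spec.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: `spec`; `subjects`, a list of
#'   `(subject_id, series, snap, true_class)`; `clinical`, the raw clinical
#'   data.frame consumed by [build_cohort_table()] (with `NA` cells if
#'   `missing_rate > 0`); `truth`, a data.frame of generator classes.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  if (spec$prevalence > 0 && spec$n_positive == 0L)
    stop("infeasible spec: positive prevalence rounds to 0 subjects")
  classes <- integer(n)
  if (spec$n_positive > 0L)
    classes[with_seed(spec$seed, sample.int(n, spec$n_positive))] <- 1L
  ids <- sprintf("S%03d", seq_len(n))
  subjects <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sig <- generate_subject_signal(classes[i], spec, subject_seed(spec$seed, i, 1L))
    snap <- generate_snapiv(classes[i], spec, subject_seed(spec$seed, i, 2L))
    demo <- generate_demographics(subject_seed(spec$seed, i, 3L))
    subjects[[i]] <- list(subject_id = ids[i], series = sig, snap = snap,
                          true_class = classes[i])
    row <- data.frame(subject_id = ids[i], sex = demo$sex, age = demo$age,
                      bmi = demo$bmi, grade = demo$grade,
                      health_state = demo$health_state,
                      diet_state = demo$diet_state,
                      parental_education = demo$parental_education,
                      stringsAsFactors = FALSE)
    row[snap_item_cols()] <- as.list(snap)
    rows[[i]] <- row
  }
  clinical <- do.call(rbind, rows)
  if (spec$missing_rate > 0) {
    demo_cols <- c("bmi", "health_state", "diet_state", "parental_education")
    clinical <- with_seed(subject_seed(spec$seed, 0L, 4L), {
      for (col in demo_cols) {
        hit <- stats::runif(n) < spec$missing_rate
        # keep at least one observed value per column
        if (all(hit)) hit[1] <- FALSE
        clinical[[col]][hit] <- NA
      }
      clinical
    })
  }
  structure(list(spec = spec, subjects = subjects, clinical = clinical,
                 truth = data.frame(subject_id = ids, true_class = classes,
                                    stringsAsFactors = FALSE)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d positive), %g min @ %g Hz, effect %g, snap shift %g, seed %d\n",
              x$spec$n_subjects, sum(x$truth$true_class),
              x$spec$minutes_per_subject, x$spec$rate_hz, x$spec$effect_size,
              x$spec$snap_shift, x$spec$seed))
  invisible(x)
}
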