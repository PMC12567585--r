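#' Stratified subject-level train/validation/test split
#'
#' Partitions subjects (never individual sequences) into three disjoint
#' sets, preserving the class mix. Within each class, per-set quotas are
#' `fractions * n_class` rounded by the largest-remainder rule (ties broken
#' in set order train, val, test), which keeps every set's positive count
#' within one of exact proportionality. Assignment of individual subjects
#' to quotas is a seeded shuffle, so the plan is deterministic given the
#' seed.
#'
#' @param subjects Vector of subject identifiers.
#' @param labels 0/1 labels, same length.
#' @param fractions Length-3 non-negative fractions summing to 1
#'   (default `c(0.55, 0.15, 0.30)`).
#' @param seed Integer seed.
#' @return Object of class `split_plan`: list with `train`, `val`, `test`
#'   id vectors and the `fractions` used.
#' @export
subject_split <- function(subjects, labels, fractions = c(0.55, 0.15, 0.30),
                          seed = 42) {
  stopifnot(length(subjects) == length(labels), all(labels %in% 0:1),
            length(fractions) == 3L, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (anyDuplicated(subjects)) stop("duplicate subject ids")
  n_sets <- sum(fractions > 0)
  sets <- list(train = character(), val = character(), test = character())
  for (cl in unique(labels)) {
    ids <- as.character(subjects[labels == cl])
    if (length(ids) < n_sets)
      stop(sprintf("class %d has %d subject(s), fewer than the %d non-empty sets; use fewer splits",
                   cl, length(ids), n_sets))
    quota <- largest_remainder(length(ids) * fractions)
    ids <- with_seed(seed + as.integer(cl), sample(ids))
    cuts <- cumsum(quota)
    sets$train <- c(sets$train, ids[seq_len(quota[1])])
    if (quota[2] > 0) sets$val <- c(sets$val, ids[(cuts[1] + 1):cuts[2]])
    if (quota[3] > 0) sets$test <- c(sets$test, ids[(cuts[2] + 1):cuts[3]])
  }
  structure(list(train = sets$train, val = sets$val, test = sets$test,
                 fractions = fractions),
            class = "split_plan")
}

# Largest-remainder (Hamilton) rounding of non-negative quotas to integers
# preserving the total; ties on remainders resolved by position order.
largest_remainder <- function(quota) {
  fl <- floor(quota + 1e-9)
  rem <- round(sum(quota)) - sum(fl)
  if (rem > 0) {
    frac <- quota - fl
    extra <- order(-frac, seq_along(quota))[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train %d / val %d / test %d subjects\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

#' Stratified k-fold assignment at subject level
#'
#' Each subject lands in exactly one fold; within each class, shuffled
#' members are dealt round-robin so per-fold class counts differ by at most
#' one. The dealing start fold is offset between classes to keep overall
#' fold sizes balanced.
#'
#' @param subjects Subject identifiers.
#' @param labels 0/1 labels.
#' @param k Number of folds (default 10). Every class must have at least
#'   `k` members.
#' @param seed Integer seed.
#' @return Named integer vector: fold index (1..k) per subject id.
#' @export
stratified_kfold <- function(subjects, labels, k = 10, seed = 42) {
  stopifnot(length(subjects) == length(labels), all(labels %in% 0:1), k >= 2)
  if (anyDuplicated(subjects)) stop("duplicate subject ids")
  fold <- integer(length(subjects))
  names(fold) <- as.character(subjects)
  offset <- 0L
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop(sprintf("class %d has %d subject(s) < k = %d folds", cl,
                   length(idx), k))
    ids <- with_seed(seed + 100L + as.integer(cl), sample(idx))
    fold[ids] <- ((seq_along(ids) - 1L + offset) %% k) + 1L
    offset <- (offset + length(ids)) %% k
  }
  fold
}
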