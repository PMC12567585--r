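# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# the default study-condition cohort (50 subjects, effect 2, shift 0.9)
default_cohort <- function() cached("default_cohort",
                                    generate_cohort(cohort_spec()))

default_sequences <- function() cached("default_sequences",
  encode_cohort(default_cohort(), window_config(image_size = 32)))

# a small random image sequence for model-level tests
random_gaf_image <- function(size = 32) {
  m <- matrix(stats::runif(size * size), size)
  m <- (m + t(m)) / 2
  structure(list(matrix = m, window_start = 0L, window_end = 1000L),
            class = "gaf_image")
}

random_sequence <- function(id = "S001", n_frames = 5, size = 32) {
  structure(list(frames = replicate(n_frames, list(random_gaf_image(size)),
                                    simplify = FALSE),
                 subject_id = id, sequence_index = 1L,
                 image_size = as.integer(size), channels = 3L,
                 channel_mode = "replicate"),
            class = "image_sequence")
}

random_samples <- function(n = 4, d_tab = 6, size = 32, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("R%03d", seq_len(n))
    seqs <- lapply(ids, random_sequence, size = size)
    feat <- matrix(stats::rnorm(n * d_tab), n, dimnames = list(ids, NULL))
    labs <- stats::setNames(rep_len(c(0L, 1L), n), ids)
    build_samples(seqs, feat, labs, vit_config_tiny())
  })
}
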