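test_that("ENMO removes the static gravity component", {
  ts <- triaxial_series(x = c(0, 0.6, 1), y = c(0, 0.8, 2), z = c(1, 0, 2))
  expect_equal(compute_enmo(ts)$values, c(0, 0, 2))
  # any constant-norm-1 signal has ENMO identically 0
  withr::with_seed(11, {
    u <- matrix(rnorm(3 * 50), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    ts2 <- triaxial_series(u[, 1], u[, 2], u[, 3])
    expect_equal(compute_enmo(ts2)$values, rep(0, 50), tolerance = 1e-12)
  })
  # clipping truncates sub-1g magnitudes at zero
  ts3 <- triaxial_series(c(0, 0), c(0, 0), c(0.5, 1.2))
  expect_equal(compute_enmo(ts3, clip_negative = TRUE)$values, c(0, 0.2))
  expect_equal(compute_enmo(ts3)$values, c(-0.5, 0.2))
})

test_that("triaxial ingestion rejects non-finite samples by index", {
  expect_error(triaxial_series(c(0, NA, 1), c(0, 0, 0), c(1, 1, 1)),
               "sample index 2")
  expect_error(triaxial_series(c(0, Inf), c(0, 0), c(1, 1)), "sample index 2")
  expect_error(triaxial_series(1, 1, 1), "length >= 2")
})

test_that("min-max normalisation attains both endpoints and rejects constants", {
  expect_equal(minmax_normalise(c(0, 5, 10))$values, c(-1, 0, 1))
  expect_equal(minmax_normalise(c(-1, 1))$values, c(-1, 1))
  expect_error(minmax_normalise(c(3, 3, 3)), "degenerate")
  withr::with_seed(2, {
    for (i in 1:20) {
      v <- rnorm(sample(2:100, 1))
      out <- minmax_normalise(v)$values
      expect_equal(range(out), c(-1, 1))
    }
  })
  # source range retained for traceability
  nm <- minmax_normalise(c(2, 4, 8))
  expect_equal(c(nm$source_min, nm$source_max), c(2, 8))
})

test_that("polar encoding is the inverse-cosine map with time radius", {
  p <- polar_encode(c(1, 0, -1))
  expect_equal(p$theta, c(0, pi / 2, pi))
  expect_equal(polar_encode(rep(0, 4))$radius[2], 0.5)
  withr::with_seed(3, {
    v <- runif(64, -1, 1)
    p <- polar_encode(v)
    expect_equal(cos(p$theta), v, tolerance = 1e-12)
    expect_true(all(p$theta >= 0 & p$theta <= pi))
    expect_true(all(diff(p$radius) > 0))
    expect_equal(p$radius[length(v)], 1)
  })
  expect_error(polar_encode(c(0, 1.1)), "outside")
  expect_equal(polar_encode(c(0, 1 + 1e-12))$theta[2], 0)  # clamped
})

test_that("GAF matrix matches its closed form and encodes temporal order", {
  expect_equal(gaf_matrix(polar_encode(c(1, -1))),
               matrix(c(1, -1, -1, 1), 2))
  expect_equal(gaf_matrix(polar_encode(c(0, 0))), matrix(-1, 2, 2))
  withr::with_seed(4, {
    for (i in 1:25) {
      v <- runif(sample(3:64, 1), -1, 1)
      G <- gaf_matrix(polar_encode(v))
      expect_equal(G, gaf_oracle(v), tolerance = 1e-10)
      expect_equal(G, t(G))
      expect_equal(diag(G), 2 * v^2 - 1, tolerance = 1e-12)
      expect_true(all(G >= -1 - 1e-12 & G <= 1 + 1e-12))
    }
  })
  # order sensitivity: reversal of a non-palindromic series changes the field
  v <- c(-1, -0.2, 0.4, 1)
  expect_false(isTRUE(all.equal(gaf_matrix(polar_encode(v)),
                                gaf_matrix(polar_encode(rev(v))))))
  expect_error(gaf_matrix(numeric(0)), "empty")
})

test_that("unit rescale is the exact affine map and preserves symmetry", {
  G <- matrix(c(-1, 0, 0, 1), 2)
  img <- rescale_unit(G)
  expect_equal(img$matrix, matrix(c(0, 0.5, 0.5, 1), 2))
  withr::with_seed(5, {
    v <- runif(16, -1, 1)
    G <- gaf_matrix(polar_encode(v))
    img <- rescale_unit(G)$matrix
    expect_equal(img, t(img))
    expect_equal(2 * img - 1, G, tolerance = 1e-12)   # round trip
  })
  expect_error(rescale_unit(matrix(c(0, 1.5), 1)), "outside")
})

test_that("PAA downsampling averages fractional bins and preserves the mean", {
  expect_equal(paa_downsample(c(1, 1, 2, 2), 2), c(1, 2))
  expect_equal(paa_downsample(c(1, 2, 3), 2), c(4 / 3, 8 / 3))
  v <- rnorm(17)
  expect_equal(paa_downsample(v, 17), v)   # identity at own length
  withr::with_seed(6, {
    for (i in 1:20) {
      n <- sample(5:200, 1)
      m <- sample(seq_len(n), 1)
      v <- rnorm(n)
      out <- paa_downsample(v, m)
      expect_equal(out, paa_oracle(v, m), tolerance = 1e-10)
      expect_equal(mean(out), mean(v), tolerance = 1e-10)
    }
  })
  expect_error(paa_downsample(1:3, 4), "no upsampling")
})

test_that("windowing groups consecutive non-overlapping windows into sequences", {
  spec <- cohort_spec(minutes_per_subject = 2, seed = 9)
  sig <- generate_subject_signal(0L, spec, 123L)
  enmo <- compute_enmo(sig)
  cfg <- window_config(window_sec = 10, image_size = 32, frames_per_sample = 5)
  # 120 s at 100 Hz = 12 windows of 1000 samples -> floor(12 / 5) = 2
  seqs <- window_to_sequence(enmo, cfg, subject_id = "A")
  expect_length(seqs, 2)
  expect_length(seqs[[1]]$frames, 5)
  # windows are half-open, consecutive, non-overlapping
  w1 <- seqs[[1]]$frames[[1]][[1]]
  w2 <- seqs[[1]]$frames[[2]][[1]]
  expect_equal(c(w1$window_start, w1$window_end), c(0, 1000))
  expect_equal(c(w2$window_start, w2$window_end), c(1000, 2000))
  # 9 windows -> exactly 1 sequence, 4 leftover windows dropped
  enmo9 <- structure(list(values = enmo$values[1:9000], rate_hz = 100),
                     class = "enmo_series")
  expect_length(window_to_sequence(enmo9, cfg), 1)
  # shorter than one full sequence -> empty with a warning, not an error
  enmo_short <- structure(list(values = enmo$values[1:3000], rate_hz = 100),
                          class = "enmo_series")
  expect_warning(out <- window_to_sequence(enmo_short, cfg), "too short")
  expect_length(out, 0)
  # every frame is a symmetric [0, 1] image of the configured side
  img <- w1$matrix
  expect_equal(dim(img), c(32, 32))
  expect_true(all(img >= 0 & img <= 1))
  expect_equal(img, t(img))
})

test_that("per-axis mode produces three distinct channels", {
  spec <- cohort_spec(minutes_per_subject = 1, seed = 5)
  sig <- generate_subject_signal(1L, spec, 77L)
  cfg <- window_config(window_sec = 10, image_size = 32,
                       channel_mode = "per_axis")
  seqs <- window_to_sequence(compute_enmo(sig), cfg, "A", series = sig)
  expect_length(seqs[[1]]$frames[[1]], 3)
  ch <- seqs[[1]]$frames[[1]]
  expect_false(isTRUE(all.equal(ch[[1]]$matrix, ch[[3]]$matrix)))
})
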