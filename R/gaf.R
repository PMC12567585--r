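#' Construct a triaxial accelerometer series
#'
#' Container for a wrist-accelerometer recording: three acceleration axes in
#' g units sampled at a fixed rate. All downstream encoding starts from this
#' object.
#'
#' @param x,y,z Numeric vectors of equal length (>= 2), acceleration in g.
#' @param rate_hz Sampling frequency in Hz (default 100).
#' @param timestamps Optional numeric vector of seconds, monotone increasing.
#'   Defaults to an even grid at `rate_hz`.
#' @return An object of class `triaxial_series` with fields `timestamps`,
#'   `x`, `y`, `z`, `rate_hz`.
#' @examples
#' ts <- triaxial_series(x = c(0, 0.1), y = c(0, 0), z = c(1, 1))
#' @export
triaxial_series <- function(x, y, z, rate_hz = 100, timestamps = NULL) {
  n <- length(x)
  if (n < 2L || length(y) != n || length(z) != n)
    stop("x, y, z must have identical length >= 2")
  for (ax in list(x = x, y = y, z = z)) {
    bad <- which(!is.finite(ax))
    if (length(bad))
      stop(sprintf("non-finite acceleration value at sample index %d", bad[1]))
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  if (is.null(timestamps)) {
    timestamps <- (seq_len(n) - 1) / rate_hz
  } else {
    if (length(timestamps) != n) stop("timestamps length mismatch")
    if (any(!is.finite(timestamps)) || any(diff(timestamps) <= 0))
      stop("timestamps must be finite and strictly increasing")
  }
  structure(list(timestamps = timestamps, x = as.numeric(x),
                 y = as.numeric(y), z = as.numeric(z),
                 rate_hz = as.numeric(rate_hz)),
            class = "triaxial_series")
}

#' @export
print.triaxial_series <- function(x, ...) {
  cat(sprintf("<triaxial_series> %d samples @ %g Hz (%.1f s)\n",
              length(x$x), x$rate_hz, length(x$x) / x$rate_hz))
  invisible(x)
}

#' Euclidean Norm Minus One (ENMO)
#'
#' Computes `sqrt(x^2 + y^2 + z^2) - 1` per sample, the magnitude of the
#' acceleration vector with the static 1 g gravity contribution removed.
#' A stationary device in any orientation yields ENMO of zero.
#'
#' @param series A [triaxial_series()].
#' @param clip_negative If `TRUE`, negative ENMO values (norm below 1 g,
#'   e.g. during free-fall-like phases or from sensor noise) are truncated at
#'   zero, the convention of much accelerometry software. Default `FALSE`
#'   keeps the signed value.
#' @return An object of class `enmo_series` with fields `values` and
#'   `rate_hz`.
#' @export
compute_enmo <- function(series, clip_negative = FALSE) {
  stopifnot(inherits(series, "triaxial_series"))
  vals <- sqrt(series$x^2 + series$y^2 + series$z^2) - 1
  bad <- which(!is.finite(vals))
  if (length(bad))
    stop(sprintf("non-finite ENMO at sample index %d", bad[1]))
  if (isTRUE(clip_negative)) vals <- pmax(vals, 0)
  structure(list(values = vals, rate_hz = series$rate_hz),
            class = "enmo_series")
}

#' Min-max normalise a signal to [-1, 1]
#'
#' Rescales a sequence to the unit symmetric interval,
#' `(v - min) / (max - min) * 2 - 1`, the range required by the polar
#' (inverse-cosine) encoding. The output always attains both -1 and +1 on
#' non-constant input; a constant sequence is rejected rather than silently
#' dividing by zero.
#'
#' @param values Numeric vector, length >= 2.
#' @return Object of class `normalised_series`: `values` in `[-1, 1]` plus
#'   the `source_min` / `source_max` used, retained for traceability.
#' @export
minmax_normalise <- function(values) {
  if (inherits(values, "enmo_series")) values <- values$values
  if (length(values) < 2L) stop("need at least 2 values to normalise")
  if (any(!is.finite(values))) stop("non-finite values cannot be normalised")
  r <- range(values)
  if (r[1] == r[2])
    stop("degenerate input: constant sequence has no dynamic range")
  v <- (values - r[1]) / (r[2] - r[1]) * 2 - 1
  structure(list(values = v, source_min = r[1], source_max = r[2]),
            class = "normalised_series")
}

#' Polar encoding of a normalised series
#'
#' Maps each normalised amplitude to an angle `theta = arccos(v)` and each
#' time index to a radius `r = t/T`, so the series lives on a polar grid
#' where angle encodes amplitude and radius encodes time order.
#'
#' @param norm A [minmax_normalise()] result, or a numeric vector already in
#'   `[-1, 1]`.
#' @param tol Values outside `[-1, 1]` by at most `tol` are clamped;
#'   larger excursions are an error.
#' @return Object of class `polar_series` with `theta` (radians, in
#'   `[0, pi]`) and `radius` (strictly increasing, `1/T` to 1).
#' @export
polar_encode <- function(norm, tol = 1e-8) {
  v <- if (inherits(norm, "normalised_series")) norm$values else as.numeric(norm)
  if (!length(v)) stop("empty input")
  over <- max(0, max(v) - 1, -1 - min(v))
  if (over > tol)
    stop(sprintf("value outside [-1, 1] by %.3g (> tol %.3g)", over, tol))
  v <- pmin(pmax(v, -1), 1)
  T <- length(v)
  structure(list(theta = acos(v), radius = seq_len(T) / T),
            class = "polar_series")
}

#' Gramian Angular Field matrix
#'
#' Builds the `T x T` Gramian `G[i, j] = cos(theta_i + theta_j)` from the
#' polar angles. The matrix is symmetric with entries in `[-1, 1]`; its
#' diagonal is `cos(2 theta_i) = 2 v_i^2 - 1`. Unlike cumulative summaries,
#' the field is sensitive to temporal order, which is what lets downstream
#' image models distinguish fragmented from sustained activity with equal
#' total intensity.
#'
#' @param polar A [polar_encode()] result (or numeric vector of angles).
#' @return A plain numeric `T x T` matrix in `[-1, 1]`.
#' @export
gaf_matrix <- function(polar) {
  theta <- if (inherits(polar, "polar_series")) polar$theta else as.numeric(polar)
  if (!length(theta)) stop("empty input")
  cos(outer(theta, theta, `+`))
}

#' Rescale a GAF matrix to the unit interval
#'
#' Applies the data-independent affine map `(G + 1) / 2`, taking the
#' Gramian's `[-1, 1]` range to `[0, 1]` pixel values. Being data
#' independent (as opposed to per-image min-max), the map is exactly
#' invertible and pixel values are comparable across images.
#'
#' @param G Numeric matrix with entries in `[-1, 1]` (a [gaf_matrix()]).
#' @param window_start,window_end Optional half-open sample-index window
#'   `[start, end)` (0-based) into the source series, kept for provenance.
#' @param tol Entries outside `[-1, 1]` by more than `tol` are an error.
#' @return Object of class `gaf_image`: fields `matrix` (values in
#'   `[0, 1]`), `window_start`, `window_end`.
#' @export
rescale_unit <- function(G, window_start = NA_integer_, window_end = NA_integer_,
                         tol = 1e-8) {
  if (!is.matrix(G) || !nrow(G)) stop("G must be a non-empty matrix")
  over <- max(0, max(G) - 1, -1 - min(G))
  if (over > tol)
    stop(sprintf("matrix entry outside [-1, 1] by %.3g", over))
  img <- (pmin(pmax(G, -1), 1) + 1) / 2
  structure(list(matrix = img, window_start = window_start,
                 window_end = window_end),
            class = "gaf_image")
}

#' Piecewise aggregate approximation (PAA) downsampling
#'
#' Reduces a series to `target_len` values by averaging over equal-measure
#' bins. Bin boundaries may fall inside a sample; the straddled sample then
#' contributes to both bins with weight proportional to the overlap, so the
#' overall mean is preserved exactly. Used to fit an analysis window into a
#' fixed GAF image side length.
#'
#' @param values Numeric vector.
#' @param target_len Output length, `1 <= target_len <= length(values)`.
#'   Upsampling is not supported.
#' @return Numeric vector of length `target_len`.
#' @export
paa_downsample <- function(values, target_len) {
  n <- length(values)
  m <- as.integer(target_len)
  if (is.na(m) || m < 1L) stop("target_len must be >= 1")
  if (m > n) stop("target_len exceeds input length (no upsampling)")
  if (m == n) return(as.numeric(values))
  bw <- n / m
  out <- numeric(m)
  for (j in seq_len(m)) {
    a <- (j - 1) * bw
    b <- j * bw
    i0 <- floor(a + 1e-12) + 1L
    i1 <- min(n, ceiling(b - 1e-12))
    idx <- i0:i1
    w <- pmin(idx, b) - pmax(idx - 1, a)
    out[j] <- sum(values[idx] * w) / bw
  }
  out
}

#' Windowing configuration for GAF sequence encoding
#'
#' @param window_sec Window duration in seconds (default 10).
#' @param image_size GAF image side length; each window is PAA-reduced to
#'   this many points (default 224, matching common pretrained backbones;
#'   use 32 with the tiny model preset).
#' @param frames_per_sample Consecutive non-overlapping windows grouped into
#'   one model input sequence (default 5).
#' @param channel_mode `"replicate"` copies the single ENMO-GAF channel to
#'   3 channels; `"per_axis"` builds one GAF per raw axis (x, y, z).
#' @param clip_negative Passed to [compute_enmo()].
#' @return A `window_config` list.
#' @export
window_config <- function(window_sec = 10, image_size = 224,
                          frames_per_sample = 5,
                          channel_mode = c("replicate", "per_axis"),
                          clip_negative = FALSE) {
  channel_mode <- match.arg(channel_mode)
  stopifnot(window_sec > 0, image_size >= 2, frames_per_sample >= 1)
  structure(list(window_sec = window_sec, image_size = as.integer(image_size),
                 frames_per_sample = as.integer(frames_per_sample),
                 channel_mode = channel_mode,
                 clip_negative = isTRUE(clip_negative)),
            class = "window_config")
}

# one window of raw values -> gaf_image (PAA -> minmax -> polar -> GAF -> [0,1])
encode_window <- function(values, image_size, window_start, window_end) {
  v <- paa_downsample(values, min(image_size, length(values)))
  rescale_unit(gaf_matrix(polar_encode(minmax_normalise(v))),
               window_start = window_start, window_end = window_end)
}

#' Encode an ENMO series into GAF image sequences
#'
#' Splits the series into consecutive non-overlapping windows of
#' `window_sec` seconds, encodes each window as a `[0, 1]` GAF image
#' (see [encode_window] steps: PAA, min-max normalisation, polar encoding,
#' Gramian, unit rescale), and groups every `frames_per_sample` consecutive
#' windows into one image sequence. Trailing windows that do not fill a
#' complete sequence are dropped.
#'
#' @param enmo An `enmo_series` (from [compute_enmo()]).
#' @param cfg A [window_config()].
#' @param subject_id Identifier attached to each sequence.
#' @param series The source [triaxial_series()]; required when
#'   `cfg$channel_mode == "per_axis"`.
#' @return A list of `image_sequence` objects, each holding
#'   `frames_per_sample` frames. Each frame is a list of 1 (`replicate`) or
#'   3 (`per_axis`) `gaf_image` channels; `replicate` frames are expanded to
#'   3 identical channels at model input. A series shorter than one full
#'   sequence returns an empty list with a warning.
#' @export
window_to_sequence <- function(enmo, cfg = window_config(), subject_id = NA,
                               series = NULL) {
  stopifnot(inherits(enmo, "enmo_series"), inherits(cfg, "window_config"))
  w <- as.integer(round(cfg$window_sec * enmo$rate_hz))
  if (w < 2L) stop("window shorter than 2 samples")
  n <- length(enmo$values)
  n_win <- n %/% w
  n_seq <- n_win %/% cfg$frames_per_sample
  if (n_seq == 0L) {
    warning(sprintf("series too short for one sequence (%d samples < %d); returning empty",
                    n, w * cfg$frames_per_sample))
    return(list())
  }
  if (cfg$channel_mode == "per_axis" && is.null(series))
    stop("per_axis mode needs the source triaxial_series")
  out <- vector("list", n_seq)
  for (s in seq_len(n_seq)) {
    frames <- vector("list", cfg$frames_per_sample)
    for (f in seq_len(cfg$frames_per_sample)) {
      k <- (s - 1L) * cfg$frames_per_sample + (f - 1L)  # 0-based window index
      idx <- (k * w + 1L):((k + 1L) * w)
      if (cfg$channel_mode == "replicate") {
        frames[[f]] <- list(encode_window(enmo$values[idx], cfg$image_size,
                                          k * w, (k + 1L) * w))
      } else {
        frames[[f]] <- lapply(list(series$x, series$y, series$z), function(ax)
          encode_window(ax[idx], cfg$image_size, k * w, (k + 1L) * w))
      }
    }
    out[[s]] <- structure(list(frames = frames, subject_id = subject_id,
                               sequence_index = s,
                               image_size = cfg$image_size,
                               channels = 3L,
                               channel_mode = cfg$channel_mode),
                          class = "image_sequence")
  }
  out
}

#' @export
print.image_sequence <- function(x, ...) {
  cat(sprintf("<image_sequence> subject %s #%d: %d frames of %dx%d (%s, 3 channels)\n",
              as.character(x$subject_id), x$sequence_index, length(x$frames),
              x$image_size, x$image_size, x$channel_mode))
  invisible(x)
}

#' Encode a whole cohort of accelerometer recordings
#'
#' Applies [compute_enmo()] and [window_to_sequence()] to every subject of a
#' synthetic or ingested cohort.
#'
#' @param cohort A `synthetic_cohort` (see [generate_cohort()]) or a list of
#'   elements each holding `subject_id` and `series`.
#' @param cfg A [window_config()].
#' @return Flat list of `image_sequence` objects across all subjects.
#' @export
encode_cohort <- function(cohort, cfg = window_config()) {
  subjects <- if (!is.null(cohort$subjects)) cohort$subjects else cohort
  out <- list()
  for (sub in subjects) {
    enmo <- compute_enmo(sub$series, clip_negative = cfg$clip_negative)
    out <- c(out, window_to_sequence(enmo, cfg, subject_id = sub$subject_id,
                                     series = sub$series))
  }
  out
}
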