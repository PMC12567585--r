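#' Read a SensorLog-style accelerometer CSV
#'
#' Comma-separated, UTF-8, header row required. Timestamps may be epoch
#' seconds or ISO-8601 strings; both are normalised to seconds internally.
#' Rows with unparsable values are dropped and counted; in lenient mode
#' (default) more than 1% dropped rows raises a warning, in strict mode an
#' error. The sampling rate estimated from the timestamps is checked
#' against the declared rate within 5%.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping the roles `time`, `x`,
#'   `y`, `z` to column names in the file. The default assumes columns
#'   named `timestamp`, `x`, `y`, `z`; adjust to match your export.
#' @param rate_hz Declared sampling rate (default 100).
#' @param strict Escalate data-quality warnings to errors.
#' @return A [triaxial_series()].
#' @export
read_accelerometer_csv <- function(path,
                                   column_map = c(time = "timestamp",
                                                  x = "x", y = "y", z = "z"),
                                   rate_hz = 100, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(column_map), names(df))
  if (length(miss))
    stop(sprintf("mapped column(s) %s not in file; available: %s",
                 paste(miss, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  tm <- parse_timestamps(df[[column_map[["time"]]]])
  ax <- suppressWarnings(lapply(c("x", "y", "z"), function(a)
    as.numeric(df[[column_map[[a]]]])))
  ok <- is.finite(tm) & is.finite(ax[[1]]) & is.finite(ax[[2]]) &
    is.finite(ax[[3]])
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    msg <- sprintf("dropped %d unparsable row(s) of %d", n_drop, nrow(df))
    if (strict && n_drop / nrow(df) > 0.01) stop(msg, " (strict mode)")
    warning(msg)
  }
  tm <- tm[ok]
  if (length(tm) < 2L) stop("fewer than 2 valid rows")
  est <- 1 / stats::median(diff(tm))
  if (is.finite(est) && abs(est - rate_hz) / rate_hz > 0.05) {
    msg <- sprintf("estimated rate %.1f Hz differs from declared %g Hz by > 5%%",
                   est, rate_hz)
    if (strict) stop(msg) else warning(msg)
  }
  triaxial_series(ax[[1]][ok], ax[[2]][ok], ax[[3]][ok], rate_hz = rate_hz,
                  timestamps = tm - tm[1])
}

parse_timestamps <- function(v) {
  if (is.numeric(v)) return(as.numeric(v))
  num <- suppressWarnings(as.numeric(v))
  if (all(is.finite(num))) return(num)
  t <- suppressWarnings(as.POSIXct(v, tz = "UTC",
                                   tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                  "%Y-%m-%d %H:%M:%OS")))
  as.numeric(t)
}

#' Write a triaxial series as CSV
#'
#' Inverse of [read_accelerometer_csv()] with the default column map.
#' Values are written at full precision so a round-trip is exact.
#'
#' @param series A [triaxial_series()].
#' @param path Output path.
#' @export
write_accelerometer_csv <- function(series, path) {
  df <- data.frame(timestamp = series$timestamps, x = series$x, y = series$y,
                   z = series$z)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Read / write the per-subject clinical CSV
#'
#' One row per subject, header row, missing values as empty cells. The
#' expected encodings (sex 0 = male / 1 = female, 1-3 ordinals for the
#' socioeconomic factors, SNAP-IV items 0-3) are documented in the data
#' dictionary shipped at
#' `system.file("extdata", "clinical_dictionary.csv", package = "actimodal")`.
#'
#' @param path CSV path.
#' @return Data frame suitable for [build_cohort_table()].
#' @export
read_clinical_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

#' @rdname read_clinical_csv
#' @param clinical Data frame to write.
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, na = "")
}

#' Write a GAF image as 8-bit grayscale PNG
#'
#' Pixel value is `round(255 * v)` for matrix entry `v` in `[0, 1]`; the
#' first matrix row is the top image row (earlier time at the top). For
#' numerically exact storage use [write_gaf_archive()].
#'
#' @param img A `gaf_image` (or bare matrix in `[0, 1]`).
#' @param path Output path.
#' @export
write_gaf_png <- function(img, path) {
  m <- if (inherits(img, "gaf_image")) img$matrix else img
  png::writePNG(round(m * 255) / 255, path)
}

#' @rdname write_gaf_png
#' @return `read_gaf_png` returns the image matrix in `[0, 1]`.
#' @export
read_gaf_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}

#' Lossless archive of image sequences
#'
#' Serialises the full-precision GAF matrices (exact round-trip contract),
#' for numeric work where 8-bit PNG quantisation is unacceptable.
#'
#' @param sequences List of `image_sequence` objects.
#' @param path Output file.
#' @export
write_gaf_archive <- function(sequences, path) {
  saveRDS(sequences, path)
}

#' @rdname write_gaf_archive
#' @export
read_gaf_archive <- function(path) readRDS(path)

#' Export image sequences as PNG files plus a manifest
#'
#' Writes one grayscale PNG per frame channel and a manifest CSV recording
#' subject, sequence index, frame index, channel, source window (half-open
#' sample indices) and file path.
#'
#' @param sequences List of `image_sequence` objects.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly; also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_image_sequences <- function(sequences, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (sq in sequences) {
    for (f in seq_along(sq$frames)) {
      chans <- sq$frames[[f]]
      for (ch in seq_along(chans)) {
        fn <- sprintf("%s_seq%03d_frame%d_ch%d.png",
                      as.character(sq$subject_id), sq$sequence_index, f, ch)
        write_gaf_png(chans[[ch]], file.path(dir, fn))
        rows[[length(rows) + 1L]] <-
          data.frame(subject_id = as.character(sq$subject_id),
                     sequence_index = sq$sequence_index, frame_index = f,
                     channel = ch, window_start = chans[[ch]]$window_start,
                     window_end = chans[[ch]]$window_end,
                     path = fn, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Write metrics as JSON
#'
#' @param metrics Named list or evaluation object.
#' @param path Output path.
#' @export
write_metrics_json <- function(metrics, path) {
  if (inherits(metrics, "evaluation"))
    metrics <- list(sequence = metrics$sequence, subject = metrics$subject)
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' @rdname write_metrics_json
#' @export
read_metrics_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Export a synthetic cohort in the package's on-disk formats
#'
#' Writes one accelerometer CSV per subject, the clinical CSV, and a
#' ground-truth JSON (spec, seed, generator classes) — the same formats
#' the readers consume, so a written cohort round-trips through
#' [read_accelerometer_csv()] / [read_clinical_csv()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the directory path.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sub in cohort$subjects)
    write_accelerometer_csv(sub$series,
                            file.path(dir, paste0(sub$subject_id, "_accel.csv")))
  write_clinical_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  jsonlite::write_json(list(spec = unclass(cohort$spec),
                            truth = cohort$truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
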