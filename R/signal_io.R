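#' Raw tri-axial accelerometer recording
#'
#' Container for a uniformly sampled tri-axial acceleration trace in
#' gravitational units (g). Timestamps are implicit: sample `i` (1-based)
#' occurs at `start_time + (i - 1) / sample_rate_hz`. Times are naive local
#' time; internally they are stored as POSIXct in UTC so that no daylight
#' saving arithmetic is ever applied.
#'
#' @param xyz numeric matrix with 3 columns (x, y, z) in g, or a data.frame
#'   with columns `x`, `y`, `z`.
#' @param start_time POSIXct (length 1) or ISO 8601 string.
#' @param sample_rate_hz positive sampling frequency in Hz.
#' @param dynamic_range_g positive dynamic range of the device in g; every
#'   axis value must satisfy `|v| <= dynamic_range_g`.
#' @param device_label free-text device description.
#' @return An object of class `raw_recording`.
#' @examples
#' r <- raw_recording(cbind(0, 0, rep(1, 10)), "2022-06-01 00:00:00", 100)
#' n_samples(r)
#' @export
raw_recording <- function(xyz, start_time, sample_rate_hz,
                          dynamic_range_g = 8, device_label = "wrist") {
  if (is.data.frame(xyz)) xyz <- as.matrix(xyz[, c("x", "y", "z")])
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have exactly 3 columns (x, y, z)")
  storage.mode(xyz) <- "double"
  colnames(xyz) <- c("x", "y", "z")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a single positive number")
  }
  if (dynamic_range_g <= 0) stop("dynamic_range_g must be positive")
  if (nrow(xyz) > 0 && any(abs(xyz) > dynamic_range_g + 1e-9)) {
    stop("axis values exceed the stated dynamic range of ",
         dynamic_range_g, " g")
  }
  structure(
    list(
      xyz = xyz,
      start_time = as_naive_time(start_time),
      sample_rate_hz = as.numeric(sample_rate_hz),
      dynamic_range_g = as.numeric(dynamic_range_g),
      device_label = as.character(device_label)
    ),
    class = "raw_recording"
  )
}

# Parse a time as naive local time, represented in UTC.
as_naive_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  }
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  if (is.na(out)) out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  if (is.na(out)) stop("unparseable timestamp: ", x)
  out
}

#' @rdname raw_recording
#' @param x a `raw_recording` or `magnitude_series`.
#' @export
n_samples <- function(x) UseMethod("n_samples")

#' @export
n_samples.raw_recording <- function(x) nrow(x$xyz)

#' @export
n_samples.magnitude_series <- function(x) length(x$values_g)

#' Recording / series duration in seconds
#'
#' Duration is `n / sample_rate_hz`: each sample owns one sample period, so a
#' 24 h file at 100 Hz has 8,640,000 rows and duration 86,400 s.
#' @param x a `raw_recording` or `magnitude_series`.
#' @return duration in seconds.
#' @export
duration_s <- function(x) n_samples(x) / x$sample_rate_hz

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %s | %d samples @ %g Hz (%.1f s) | ±%g g | start %s\n",
    x$device_label, n_samples(x), x$sample_rate_hz, duration_s(x),
    x$dynamic_range_g, format(x$start_time, "%Y-%m-%d %H:%M:%OS3")
  ))
  invisible(x)
}

#' @export
`==.raw_recording` <- function(e1, e2) {
  isTRUE(all.equal(e1$xyz, e2$xyz, tolerance = 1e-9)) &&
    abs(as.numeric(e1$start_time) - as.numeric(e2$start_time)) < 1e-6 &&
    e1$sample_rate_hz == e2$sample_rate_hz &&
    e1$dynamic_range_g == e2$dynamic_range_g
}

#' Per-sample Euclidean norm of a recording
#'
#' @param recording a non-empty `raw_recording`.
#' @return A `magnitude_series`: list with `values_g` (the per-sample norm
#'   `sqrt(x^2 + y^2 + z^2)`, always >= 0), `start_time` and `sample_rate_hz`
#'   copied from the input.
#' @examples
#' r <- raw_recording(cbind(3, 4, 0), "2022-06-01 00:00:00", 100)
#' vector_magnitude(r)$values_g  # 5
#' @export
vector_magnitude <- function(recording) {
  stopifnot(inherits(recording, "raw_recording"))
  if (n_samples(recording) == 0L) stop("empty recording")
  magnitude_series(
    sqrt(rowSums(recording$xyz^2)),
    recording$start_time, recording$sample_rate_hz
  )
}

#' @rdname vector_magnitude
#' @param values_g non-negative magnitude values in g.
#' @param start_time,sample_rate_hz as in [raw_recording()].
#' @export
magnitude_series <- function(values_g, start_time, sample_rate_hz) {
  structure(
    list(values_g = as.numeric(values_g),
         start_time = as_naive_time(start_time),
         sample_rate_hz = as.numeric(sample_rate_hz)),
    class = "magnitude_series"
  )
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf("<magnitude_series> %d samples @ %g Hz, start %s\n",
              n_samples(x), x$sample_rate_hz,
              format(x$start_time, "%Y-%m-%d %H:%M:%OS3")))
  invisible(x)
}

#' Read a raw accelerometer CSV
#'
#' The dialect is defined by this package (there is no community standard for
#' raw actigraphy CSV): an optional metadata comment line
#' `# sample_rate_hz=<v>` (and optional `# dynamic_range_g=<v>`,
#' `# device_label=<text>`), then a header
#' `timestamp_iso8601,accel_x_g,accel_y_g,accel_z_g`, then time-ordered rows.
#' The sampling rate is taken from the metadata line when present and checked
#' against the rate inferred from the first two timestamps (mismatch > 1% is
#' rejected); without metadata the inferred rate is used.
#'
#' @param path path to an existing CSV file.
#' @return A [raw_recording()].
#' @export
read_raw_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 8L)
  if (length(head_lines) == 0L) stop("empty input file: ", path)
  meta_lines <- grep("^#", head_lines)
  meta <- list()
  for (ln in head_lines[meta_lines]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    meta[[trimws(key)]] <- trimws(val)
  }
  n_skip <- length(meta_lines)
  if (length(head_lines) <= n_skip) stop("empty input file: ", path)
  header <- strsplit(head_lines[n_skip + 1L], ",")[[1]]
  wanted <- c("timestamp_iso8601", "accel_x_g", "accel_y_g", "accel_z_g")
  if (!all(wanted %in% trimws(header))) {
    stop("format error: expected columns ", paste(wanted, collapse = ", "))
  }
  dt <- data.table::fread(path, skip = n_skip, header = TRUE,
                          colClasses = list(character = "timestamp_iso8601"),
                          showProgress = FALSE)
  if (nrow(dt) == 0L) stop("empty input file (no data rows): ", path)
  ts <- as.POSIXct(dt$timestamp_iso8601, tz = "UTC",
                   format = "%Y-%m-%d %H:%M:%OS")
  if (anyNA(ts)) stop("data error: unparseable timestamps")
  tnum <- as.numeric(ts)
  if (nrow(dt) > 1L) {
    if (any(diff(tnum) <= 0)) stop("data error: non-monotone timestamps")
    fs_inferred <- 1 / (tnum[2L] - tnum[1L])
    # parsed fractional seconds carry ~1e-6 s noise; snap near-integer rates
    if (abs(fs_inferred - round(fs_inferred)) / fs_inferred < 1e-4) {
      fs_inferred <- round(fs_inferred)
    }
  } else {
    fs_inferred <- NA_real_
  }
  if (!is.null(meta$sample_rate_hz)) {
    fs <- as.numeric(meta$sample_rate_hz)
    if (!is.na(fs_inferred) && abs(fs_inferred - fs) / fs > 0.01) {
      stop("format error: sampling rate inferred from timestamps (",
           signif(fs_inferred, 6), " Hz) disagrees with metadata (", fs,
           " Hz) by more than 1%")
    }
  } else {
    if (is.na(fs_inferred)) stop("format error: cannot infer sampling rate ",
                                 "from a single row without metadata")
    fs <- fs_inferred
  }
  raw_recording(
    cbind(dt$accel_x_g, dt$accel_y_g, dt$accel_z_g),
    start_time = ts[1L],
    sample_rate_hz = fs,
    dynamic_range_g = if (!is.null(meta$dynamic_range_g))
      as.numeric(meta$dynamic_range_g) else 8,
    device_label = if (!is.null(meta$device_label)) meta$device_label
      else "unknown"
  )
}

#' Write a raw accelerometer CSV
#'
#' Writes the dialect documented in [read_raw_csv()]; acceleration values are
#' written with 6 decimal places of g, which round-trips losslessly at that
#' precision.
#'
#' @param recording a non-empty [raw_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  n <- n_samples(recording)
  if (n == 0L) stop("refusing to write an empty recording")
  t0 <- as.numeric(recording$start_time)
  ts <- t0 + (seq_len(n) - 1) / recording$sample_rate_hz
  ts_str <- format(as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
                   "%Y-%m-%d %H:%M:%OS6")
  meta <- c(
    sprintf("# sample_rate_hz=%.10g", recording$sample_rate_hz),
    sprintf("# dynamic_range_g=%.10g", recording$dynamic_range_g),
    sprintf("# device_label=%s", recording$device_label)
  )
  writeLines(meta, path)
  dt <- data.table::data.table(
    timestamp_iso8601 = ts_str,
    accel_x_g = sprintf("%.6f", recording$xyz[, 1L]),
    accel_y_g = sprintf("%.6f", recording$xyz[, 2L]),
    accel_z_g = sprintf("%.6f", recording$xyz[, 3L])
  )
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Linear resampling of a recording or magnitude series
#'
#' Resamples to `target_hz` by per-axis linear interpolation between the two
#' bracketing input samples. The output grid starts at the input start time
#' and never extends past the last input sample, so output duration is at
#' most input duration. Resampling at the source rate is the identity;
#' a constant signal stays constant at any rate.
#'
#' @param x a [raw_recording()] or `magnitude_series` with >= 2 samples.
#' @param target_hz positive target rate in Hz.
#' @return object of the same class as `x` at `target_hz`.
#' @export
resample_linear <- function(x, target_hz) UseMethod("resample_linear")

resample_grid <- function(n_in, fs_in, target_hz) {
  if (n_in < 2L) stop("resampling needs at least 2 samples")
  if (target_hz <= 0) stop("target_hz must be positive")
  # output length keeps duration (n / rate) <= input duration while never
  # extrapolating past the last input sample
  n_out <- min(floor(n_in * target_hz / fs_in + 1e-9),
               floor((n_in - 1) * target_hz / fs_in + 1e-9) + 1)
  (seq_len(n_out) - 1) / target_hz
}

#' @export
resample_linear.raw_recording <- function(x, target_hz) {
  if (target_hz == x$sample_rate_hz) return(x)
  t_in <- (seq_len(n_samples(x)) - 1) / x$sample_rate_hz
  t_out <- resample_grid(n_samples(x), x$sample_rate_hz, target_hz)
  out <- vapply(1:3, function(j) {
    stats::approx(t_in, x$xyz[, j], xout = t_out, method = "linear")$y
  }, numeric(length(t_out)))
  raw_recording(out, x$start_time, target_hz, x$dynamic_range_g,
                x$device_label)
}

#' @export
resample_linear.magnitude_series <- function(x, target_hz) {
  if (target_hz == x$sample_rate_hz) return(x)
  t_in <- (seq_len(n_samples(x)) - 1) / x$sample_rate_hz
  t_out <- resample_grid(n_samples(x), x$sample_rate_hz, target_hz)
  magnitude_series(
    stats::approx(t_in, x$values_g, xout = t_out, method = "linear")$y,
    x$start_time, target_hz
  )
}

#' ENMO averaged over fixed epochs
#'
#' Euclidean Norm Minus One g: per sample, `max(norm - 1, 0)` (negatives
#' truncated to zero BEFORE averaging), scaled to milli-g and averaged over
#' consecutive non-overlapping epochs. The trailing partial epoch is
#' discarded, never padded.
#'
#' @param recording a [raw_recording()].
#' @param epoch_s epoch length in seconds (default 5); `epoch_s *
#'   sample_rate_hz` must be a whole number of samples.
#' @return data.frame with columns `epoch_start` (POSIXct) and `enmo_mg`.
#'   A recording shorter than one epoch yields zero rows with a warning.
#' @export
enmo_epochs <- function(recording, epoch_s = 5) {
  stopifnot(inherits(recording, "raw_recording"), epoch_s > 0)
  mag <- vector_magnitude(recording)
  spe <- epoch_s * recording$sample_rate_hz
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch_s * sample_rate_hz must be an integer number of samples")
  }
  spe <- as.integer(round(spe))
  n_ep <- n_samples(recording) %/% spe
  if (n_ep == 0L) {
    warning("recording shorter than one epoch; returning no epochs")
    return(data.frame(epoch_start = recording$start_time[0],
                      enmo_mg = numeric(0)))
  }
  enmo <- pmax(mag$values_g[seq_len(n_ep * spe)] - 1, 0) * 1000
  means <- colMeans(matrix(enmo, nrow = spe))
  data.frame(
    epoch_start = recording$start_time + (seq_len(n_ep) - 1L) * epoch_s,
    enmo_mg = means
  )
}
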