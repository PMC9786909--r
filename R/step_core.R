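#' Step-algorithm parameter set
#'
#' The eight thresholds defining one variant of the open wrist step-count
#' algorithm, plus the rate the algorithm operates at. Sample-unit thresholds
#' (peak window, periodicity bounds, continuity window) are expressed in
#' algorithm samples at `algorithm_rate_hz`; the input signal is resampled to
#' that rate before peak detection.
#'
#' Two published presets ship with the package (see [verisense_params()]):
#'
#' | field                       | unit      | verisense1 | verisense2 |
#' |-----------------------------|-----------|-----------:|-----------:|
#' | peak_win_samples            | samples   | 3          | 4          |
#' | min_period_samples          | samples   | 5          | 4          |
#' | max_period_samples          | samples   | 15         | 20         |
#' | similarity_threshold_g      | g         | -0.5       | -1.0       |
#' | continuity_window_samples   | samples   | 4          | 4          |
#' | continuity_count_threshold  | windows   | 4          | 4          |
#' | variance_threshold_g2       | g^2       | 0.001      | 0.01       |
#' | magnitude_threshold_g       | g         | 1.2        | 1.25       |
#'
#' @param peak_win_samples half-width (in samples) of the strict local-maximum
#'   window used for candidate peak detection.
#' @param min_period_samples,max_period_samples closed interval of admissible
#'   sample gaps between consecutive retained peaks (periodicity filter).
#' @param similarity_threshold_g non-positive threshold; consecutive peaks are
#'   "similar" iff `-|height difference| >= similarity_threshold_g`.
#' @param continuity_window_samples length (samples) of the tumbling windows
#'   used for motion recognition.
#' @param continuity_count_threshold number of "in motion" windows (out of the
#'   `2 * continuity_count_threshold` windows flanking a peak's window)
#'   required to keep the peak.
#' @param variance_threshold_g2 a window is "in motion" iff its population
#'   variance exceeds this value (g^2).
#' @param magnitude_threshold_g minimum peak height in g (raw Euclidean norm,
#'   gravity included — hence values above 1 g).
#' @param algorithm_rate_hz operating rate of the algorithm (default 15 Hz; at
#'   15 Hz the periodicity windows correspond to step intervals of roughly
#'   0.27-1.33 s, i.e. 45-225 steps/min).
#' @return An object of class `step_parameters`.
#' @export
step_parameters <- function(peak_win_samples = 4,
                            min_period_samples = 4,
                            max_period_samples = 20,
                            similarity_threshold_g = -1.0,
                            continuity_window_samples = 4,
                            continuity_count_threshold = 4,
                            variance_threshold_g2 = 0.01,
                            magnitude_threshold_g = 1.25,
                            algorithm_rate_hz = 15) {
  p <- list(
    peak_win_samples = as.integer(peak_win_samples),
    min_period_samples = as.integer(min_period_samples),
    max_period_samples = as.integer(max_period_samples),
    similarity_threshold_g = as.numeric(similarity_threshold_g),
    continuity_window_samples = as.integer(continuity_window_samples),
    continuity_count_threshold = as.integer(continuity_count_threshold),
    variance_threshold_g2 = as.numeric(variance_threshold_g2),
    magnitude_threshold_g = as.numeric(magnitude_threshold_g),
    algorithm_rate_hz = as.numeric(algorithm_rate_hz)
  )
  if (p$min_period_samples > p$max_period_samples) {
    stop("min_period_samples must not exceed max_period_samples")
  }
  if (p$similarity_threshold_g > 0) {
    stop("similarity_threshold_g must be <= 0")
  }
  pos <- c("peak_win_samples", "min_period_samples", "max_period_samples",
           "continuity_window_samples", "continuity_count_threshold",
           "variance_threshold_g2", "magnitude_threshold_g",
           "algorithm_rate_hz")
  for (f in pos) if (p[[f]] <= 0) stop(f, " must be strictly positive")
  structure(p, class = "step_parameters")
}

#' Published parameter presets
#'
#' Loads one of the two published threshold sets of the open wrist step-count
#' algorithm from the JSON files shipped in `inst/extdata/`: `"verisense1"`
#' (the original published combination) or `"verisense2"` (the refined
#' combination tuned on free-living training data). A path to a custom JSON
#' file with the same fields is also accepted.
#'
#' @param preset `"verisense1"`, `"verisense2"`, or a path to a JSON file.
#' @return A [step_parameters()] object.
#' @examples
#' verisense_params("verisense2")$magnitude_threshold_g  # 1.25
#' @export
verisense_params <- function(preset = "verisense2") {
  path <- if (file.exists(preset)) preset else {
    system.file("extdata", paste0(preset, ".json"), package = "stepsense")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown preset or missing file: ", preset)
  }
  cfg <- jsonlite::fromJSON(path)
  do.call(step_parameters, cfg[names(cfg) %in% names(formals(step_parameters))])
}

#' @export
print.step_parameters <- function(x, ...) {
  cat("<step_parameters>\n")
  for (f in names(unclass(x))) cat(sprintf("  %-28s %g\n", f, x[[f]]))
  invisible(x)
}

#' Candidate peaks / retained peaks
#'
#' A `peak_list` pairs strictly increasing sample indices (1-based, on the
#' algorithm-rate magnitude series) with the magnitude values at those
#' indices.
#'
#' @param indices strictly increasing integer sample indices.
#' @param heights_g magnitude at each index, in g.
#' @return object of class `peak_list`.
#' @export
peak_list <- function(indices = integer(0), heights_g = numeric(0)) {
  indices <- as.integer(indices)
  if (length(indices) != length(heights_g)) stop("length mismatch")
  if (length(indices) > 1L && any(diff(indices) <= 0L)) {
    stop("indices must be strictly increasing")
  }
  structure(list(indices = indices, heights_g = as.numeric(heights_g)),
            class = "peak_list")
}

#' @export
length.peak_list <- function(x) length(x$indices)

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks\n", length(x)))
  invisible(x)
}

subset_peaks <- function(peaks, keep) {
  peak_list(peaks$indices[keep], peaks$heights_g[keep])
}

#' Find candidate step peaks
#'
#' Index `i` is a candidate iff `mag[i] > mag[j]` for every `j` within
#' `peak_win_samples` of `i` (strict inequality on both sides). Plateau ties
#' never produce a candidate, and indices within `peak_win_samples` of either
#' end of the series are never candidates.
#'
#' @param mag a `magnitude_series` (see [vector_magnitude()]).
#' @param peak_win_samples positive half-width k of the comparison window.
#' @return A [peak_list()]. A series of length `<= 2 * k` yields an empty
#'   list with a warning.
#' @export
find_candidate_peaks <- function(mag, peak_win_samples) {
  stopifnot(inherits(mag, "magnitude_series"))
  k <- as.integer(peak_win_samples)
  if (k <= 0L) stop("peak_win_samples must be positive")
  v <- mag$values_g
  n <- length(v)
  if (n <= 2L * k) {
    warning("series too short for peak detection (need > 2*k samples)")
    return(peak_list())
  }
  core <- (k + 1L):(n - k)
  is_peak <- rep(TRUE, length(core))
  for (off in seq_len(k)) {
    is_peak <- is_peak & v[core] > v[core - off] & v[core] > v[core + off]
  }
  idx <- core[is_peak]
  peak_list(idx, v[idx])
}

#' Magnitude filter
#'
#' Keeps peaks whose height is at least `magnitude_threshold_g` (raw norm,
#' gravity included). Order is preserved.
#'
#' @param peaks a [peak_list()].
#' @param magnitude_threshold_g threshold in g.
#' @return filtered [peak_list()].
#' @export
filter_magnitude <- function(peaks, magnitude_threshold_g) {
  subset_peaks(peaks, peaks$heights_g >= magnitude_threshold_g)
}

#' Periodicity filter
#'
#' Walks the peaks in order, measuring the sample-index gap to the previously
#' retained peak of the current run. A peak is retained iff that gap lies in
#' the closed interval `[min_period_samples, max_period_samples]`. The first
#' peak of each run seeds the chain and is kept only if at least one
#' compliant gap follows it; a gap above the maximum starts a new run (the
#' next peak becomes a fresh tentative seed), a gap below the minimum drops
#' the current peak and leaves the chain anchor in place. An isolated peak is
#' always removed: a single event cannot exhibit periodicity.
#'
#' @param peaks a [peak_list()].
#' @param min_period_samples,max_period_samples closed gap interval, samples.
#' @return filtered [peak_list()].
#' @export
filter_periodicity <- function(peaks, min_period_samples,
                               max_period_samples) {
  if (min_period_samples > max_period_samples) stop("min > max period")
  m <- length(peaks)
  if (m < 2L) return(subset_peaks(peaks, logical(m)))
  idx <- peaks$indices
  keep <- logical(m)
  anchor <- 1L  # last peak of the current chain (retained or tentative seed)
  for (i in 2L:m) {
    gap <- idx[i] - idx[anchor]
    if (gap >= min_period_samples && gap <= max_period_samples) {
      keep[anchor] <- TRUE
      keep[i] <- TRUE
      anchor <- i
    } else if (gap > max_period_samples) {
      anchor <- i  # new run; seed retained only if a compliant gap follows
    }
    # gap < min: drop peak i, keep the anchor where it is
  }
  subset_peaks(peaks, keep)
}

#' Similarity filter
#'
#' A consecutive peak pair (p, q) is similar iff
#' `-|height(p) - height(q)| >= similarity_threshold_g`, i.e. the absolute
#' height difference is at most `|threshold|` (the threshold is printed
#' negative by convention). Peaks participating in no similar pair — in
#' particular, a lone peak — are removed.
#'
#' @param peaks a [peak_list()].
#' @param similarity_threshold_g non-positive threshold in g.
#' @return filtered [peak_list()].
#' @export
filter_similarity <- function(peaks, similarity_threshold_g) {
  if (similarity_threshold_g > 0) stop("similarity_threshold_g must be <= 0")
  m <- length(peaks)
  if (m < 2L) return(subset_peaks(peaks, logical(m)))
  similar <- -abs(diff(peaks$heights_g)) >= similarity_threshold_g
  keep <- c(similar, FALSE) | c(FALSE, similar)
  subset_peaks(peaks, keep)
}

#' Continuity (motion-recognition) filter
#'
#' The magnitude signal is partitioned into consecutive tumbling windows of
#' `continuity_window_samples` samples; a window is "in motion" iff its
#' population variance (divisor n) exceeds `variance_threshold_g2`. A peak is
#' retained iff at least `continuity_count_threshold` of the
#' `2 * continuity_count_threshold` full windows flanking the peak's own
#' window (the `continuity_count_threshold` windows on each side, own window
#' excluded) are in motion. Windows beyond either end of the signal, and the
#' trailing partial window, count as not in motion.
#'
#' @param peaks a [peak_list()] detected on `mag`.
#' @param mag the `magnitude_series` the peaks were detected on.
#' @param continuity_window_samples window length in samples.
#' @param continuity_count_threshold required number of in-motion windows.
#' @param variance_threshold_g2 motion variance threshold (g^2).
#' @return filtered [peak_list()].
#' @export
filter_continuity <- function(peaks, mag, continuity_window_samples,
                              continuity_count_threshold,
                              variance_threshold_g2) {
  stopifnot(inherits(mag, "magnitude_series"))
  w <- as.integer(continuity_window_samples)
  cth <- as.integer(continuity_count_threshold)
  m <- length(peaks)
  if (m == 0L) return(peaks)
  n_win <- length(mag$values_g) %/% w
  if (n_win == 0L) return(subset_peaks(peaks, logical(m)))
  vmat <- matrix(mag$values_g[seq_len(n_win * w)], nrow = w)
  mu <- colMeans(vmat)
  in_motion <- (colMeans(vmat^2) - mu^2) > variance_threshold_g2
  win_of <- (peaks$indices - 1L) %/% w + 1L
  offs <- c(-(cth:1L), 1L:cth)
  keep <- vapply(win_of, function(wi) {
    nb <- wi + offs
    nb <- nb[nb >= 1L & nb <= n_win]
    sum(in_motion[nb]) >= cth
  }, logical(1))
  subset_peaks(peaks, keep)
}

#' Time-stamped step events
#'
#' @param times POSIXct step timestamps, strictly increasing.
#' @param source_params the [step_parameters()] that produced them.
#' @return object of class `step_events`.
#' @export
step_events <- function(times, source_params = NULL) {
  times <- as.POSIXct(as.numeric(times), origin = "1970-01-01", tz = "UTC")
  if (length(times) > 1L && any(diff(as.numeric(times)) <= 0)) {
    stop("step times must be strictly increasing")
  }
  structure(list(times = times, source_params = source_params),
            class = "step_events")
}

#' @export
length.step_events <- function(x) length(x$times)

#' @export
print.step_events <- function(x, ...) {
  cat(sprintf("<step_events> %d steps\n", length(x)))
  invisible(x)
}

# Full filter pipeline on an algorithm-rate magnitude series. Shared by
# count_steps() and tune_parameters() (which precomputes the resampled
# magnitude once per recording).
count_steps_mag <- function(mag, params) {
  if (n_samples(mag) < params$continuity_window_samples) {
    warning("recording shorter than one continuity window; 0 steps")
    return(peak_list())
  }
  if (n_samples(mag) <= 2L * params$peak_win_samples) {
    warning("recording too short for peak detection; 0 steps")
    return(peak_list())
  }
  pk <- find_candidate_peaks(mag, params$peak_win_samples)
  pk <- filter_magnitude(pk, params$magnitude_threshold_g)
  pk <- filter_periodicity(pk, params$min_period_samples,
                           params$max_period_samples)
  pk <- filter_similarity(pk, params$similarity_threshold_g)
  filter_continuity(pk, mag, params$continuity_window_samples,
                    params$continuity_count_threshold,
                    params$variance_threshold_g2)
}

#' Count steps in a raw recording
#'
#' Runs the full staged algorithm: Euclidean norm, linear resampling to the
#' algorithm rate, candidate peak detection, then the magnitude, periodicity,
#' similarity and continuity filters in that order. Every surviving peak
#' becomes one step event stamped at its sample time. Deterministic for a
#' fixed input and parameter set.
#'
#' @param recording a non-empty [raw_recording()].
#' @param params a [step_parameters()] object (default: the refined preset).
#' @return A [step_events()] object.
#' @examples
#' bout <- simulate_bout(gait_bout(cadence_spm = 120, duration_s = 30),
#'                       seed = 1)
#' length(count_steps(bout$recording, verisense_params("verisense2")))
#' @export
count_steps <- function(recording, params = verisense_params("verisense2")) {
  stopifnot(inherits(recording, "raw_recording"),
            inherits(params, "step_parameters"))
  if (n_samples(recording) == 0L) stop("empty recording")
  mag <- vector_magnitude(recording)
  if (mag$sample_rate_hz != params$algorithm_rate_hz) {
    if (n_samples(mag) < 2L) {
      warning("recording too short to resample; 0 steps")
      return(step_events(numeric(0), params))
    }
    mag <- resample_linear(mag, params$algorithm_rate_hz)
  }
  pk <- count_steps_mag(mag, params)
  t0 <- as.numeric(mag$start_time)
  step_events(t0 + (pk$indices - 1L) / mag$sample_rate_hz, params)
}
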