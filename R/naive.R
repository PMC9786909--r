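#' Naive reference step counter (test oracle)
#'
#' A deliberately simple, loop-based re-implementation of the same contract
#' as [count_steps()]: per-sample norm by explicit loop, linear resampling by
#' explicit bracketing, an exhaustive O(n*k) candidate scan, and each filter
#' written as its own plain loop. It shares no code with the vectorised path
#' and exists so the two can be checked against each other; it is quadratic
#' in places and should only be run on short inputs.
#'
#' @inheritParams count_steps
#' @return A [step_events()] object.
#' @export
naive_count_steps <- function(recording,
                              params = verisense_params("verisense2")) {
  stopifnot(inherits(recording, "raw_recording"))
  n_in <- nrow(recording$xyz)
  if (n_in == 0L) stop("empty recording")

  # per-sample Euclidean norm, scalar loop
  mag_in <- numeric(n_in)
  for (i in seq_len(n_in)) {
    mag_in[i] <- sqrt(recording$xyz[i, 1]^2 + recording$xyz[i, 2]^2 +
                        recording$xyz[i, 3]^2)
  }

  fs_in <- recording$sample_rate_hz
  fs <- params$algorithm_rate_hz
  if (fs_in == fs) {
    v <- mag_in
  } else {
    if (n_in < 2L) {
      warning("recording too short to resample; 0 steps")
      return(step_events(numeric(0), params))
    }
    n_out <- min(floor(n_in * fs / fs_in + 1e-9),
                 floor((n_in - 1) * fs / fs_in + 1e-9) + 1)
    v <- numeric(n_out)
    for (i in seq_len(n_out)) {
      t <- (i - 1) / fs
      lo <- floor(t * fs_in) + 1
      if (lo >= n_in) {
        v[i] <- mag_in[n_in]
      } else {
        frac <- t * fs_in - (lo - 1)
        v[i] <- (1 - frac) * mag_in[lo] + frac * mag_in[lo + 1]
      }
    }
  }
  n <- length(v)

  k <- params$peak_win_samples
  w <- params$continuity_window_samples
  if (n < w || n <= 2L * k) {
    warning("recording too short; 0 steps")
    return(step_events(numeric(0), params))
  }

  # exhaustive strict-local-maximum scan
  cand <- integer(0)
  for (i in (k + 1L):(n - k)) {
    ok <- TRUE
    for (j in (i - k):(i + k)) {
      if (j != i && v[j] >= v[i]) { ok <- FALSE; break }
    }
    if (ok) cand <- c(cand, i)
  }

  # magnitude
  cand <- cand[v[cand] >= params$magnitude_threshold_g]

  # periodicity: gap to the previously retained peak within [min, max];
  # run seeds retained only once a compliant gap follows.
  keep <- rep(FALSE, length(cand))
  if (length(cand) >= 2L) {
    anchor <- 1L
    for (i in 2L:length(cand)) {
      gap <- cand[i] - cand[anchor]
      if (gap >= params$min_period_samples &&
          gap <= params$max_period_samples) {
        keep[anchor] <- TRUE
        keep[i] <- TRUE
        anchor <- i
      } else if (gap > params$max_period_samples) {
        anchor <- i
      }
    }
  }
  cand <- cand[keep]

  # similarity: keep peaks in at least one similar consecutive pair
  if (length(cand) >= 2L) {
    sim_prev <- rep(FALSE, length(cand))
    sim_next <- rep(FALSE, length(cand))
    for (i in seq_len(length(cand) - 1L)) {
      d <- abs(v[cand[i + 1L]] - v[cand[i]])
      if (-d >= params$similarity_threshold_g) {
        sim_next[i] <- TRUE
        sim_prev[i + 1L] <- TRUE
      }
    }
    cand <- cand[sim_prev | sim_next]
  } else {
    cand <- integer(0)
  }

  # continuity: population variance of tumbling windows, counted over the
  # cth windows on each side of the peak's own window
  n_win <- n %/% w
  motion <- logical(n_win)
  for (wi in seq_len(n_win)) {
    seg <- v[((wi - 1L) * w + 1L):(wi * w)]
    mu <- sum(seg) / w
    motion[wi] <- sum((seg - mu)^2) / w > params$variance_threshold_g2
  }
  cth <- params$continuity_count_threshold
  keep <- rep(FALSE, length(cand))
  for (i in seq_along(cand)) {
    wi <- (cand[i] - 1L) %/% w + 1L
    cnt <- 0L
    for (d in c(-(cth:1L), 1L:cth)) {
      nb <- wi + d
      if (nb >= 1L && nb <= n_win && motion[nb]) cnt <- cnt + 1L
    }
    keep[i] <- cnt >= cth
  }
  cand <- cand[keep]

  t0 <- as.numeric(recording$start_time)
  step_events(t0 + (cand - 1L) / fs, params)
}
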