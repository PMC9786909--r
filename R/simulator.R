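# Fixed synthetic-signal conventions (documented in the methods vignette):
# - each step contributes a raised-cosine magnitude pulse of half-width
#   0.12 s; at 15 Hz this keeps the sampled peak >= ~0.8 x nominal amplitude
#   for cadences up to 140 steps/min, so a 0.4 g swing clears the 1.25 g
#   magnitude threshold after resampling;
# - acceleration is distributed over the axes by a fixed unit vector, so the
#   per-sample Euclidean norm equals the programmed magnitude envelope
#   exactly (before noise).
PULSE_HALF_WIDTH_S <- 0.12
GAIT_AXIS <- c(1, 2, 2) / 3
ARTEFACT_AXIS <- c(2, -1, 2) / 3

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Gait bout specification
#'
#' Describes one continuous stepping bout: the programmed step count is
#' `round(cadence_spm * duration_s / 60)` and each step is a raised-cosine
#' magnitude pulse peaking at `1 + swing_amplitude_g` (gravity baseline plus
#' arm swing). `harmonic_ratio` sets the depth (relative to the swing
#' amplitude) of the mid-swing unloading trough between steps — a broad
#' raised-cosine dip below 1 g at half-period that doubles the envelope's
#' fundamental (second-harmonic content) and keeps the signal in motion
#' between impact peaks, as real wrist gait is. Being a minimum, the trough
#' can never register as a candidate peak. `phase_jitter_sd` perturbs each
#' step time by a Gaussian of that SD.
#'
#' @param cadence_spm stepping rate in steps/min, in (20, 240).
#' @param duration_s bout length in seconds.
#' @param swing_amplitude_g peak magnitude above the 1 g baseline, in g;
#'   0 gives a degenerate constant-1-g bout with no detectable steps.
#' @param harmonic_ratio second-harmonic content in [0, 1]: relative depth
#'   of the mid-swing trough (default 0.7).
#' @param phase_jitter_sd SD of the per-step timing jitter, seconds.
#' @param start_offset_s bout onset relative to the scenario start, seconds.
#' @return object of class `gait_bout`.
#' @export
gait_bout <- function(cadence_spm, duration_s, swing_amplitude_g = 0.6,
                      harmonic_ratio = 0.7, phase_jitter_sd = 0.01,
                      start_offset_s = 0) {
  if (cadence_spm <= 20 || cadence_spm >= 240) {
    stop("cadence_spm must lie in (20, 240)")
  }
  if (duration_s <= 0) stop("duration_s must be positive")
  if (swing_amplitude_g < 0) stop("swing_amplitude_g must be >= 0")
  if (harmonic_ratio < 0 || harmonic_ratio > 1) {
    stop("harmonic_ratio must be in [0, 1]")
  }
  if (phase_jitter_sd < 0) stop("phase_jitter_sd must be >= 0")
  structure(
    list(cadence_spm = cadence_spm, duration_s = duration_s,
         swing_amplitude_g = swing_amplitude_g,
         harmonic_ratio = harmonic_ratio,
         phase_jitter_sd = phase_jitter_sd,
         start_offset_s = start_offset_s),
    class = "gait_bout"
  )
}

#' @rdname gait_bout
#' @param x a `gait_bout`.
#' @export
programmed_steps <- function(x) {
  round(x$cadence_spm * x$duration_s / 60)
}

# Pulse table of one bout, times relative to bout start. Consumes RNG for
# the phase jitter.
bout_pulses <- function(spec) {
  n <- programmed_steps(spec)
  period <- 60 / spec$cadence_spm
  times <- (seq_len(n) - 0.5) * period
  if (spec$phase_jitter_sd > 0 && n > 0) {
    times <- sort(times + stats::rnorm(n, 0, spec$phase_jitter_sd))
  }
  times <- pmin(pmax(times, PULSE_HALF_WIDTH_S),
                spec$duration_s - PULSE_HALF_WIDTH_S)
  main <- data.frame(time_s = times, amp = spec$swing_amplitude_g,
                     half_width = PULSE_HALF_WIDTH_S, is_step = TRUE)
  if (spec$harmonic_ratio > 0 && n > 0) {
    # mid-swing unloading trough: broad dip below baseline at half-period
    trough <- data.frame(
      time_s = pmin(times + period / 2, spec$duration_s - PULSE_HALF_WIDTH_S),
      amp = -spec$harmonic_ratio * spec$swing_amplitude_g,
      half_width = period / 4, is_step = FALSE
    )
    main <- rbind(main, trough)
  }
  main
}

# Add raised-cosine pulses into a magnitude envelope sampled at fs.
add_pulses <- function(m, fs, times, amps, half_widths) {
  n <- length(m)
  for (p in seq_along(times)) {
    h <- half_widths[p]
    lo <- max(1L, floor((times[p] - h) * fs) + 1L)
    hi <- min(n, ceiling((times[p] + h) * fs) + 1L)
    if (lo > hi) next
    tt <- (seq(lo, hi) - 1) / fs
    d <- tt - times[p]
    inside <- abs(d) < h
    m[lo:hi][inside] <- m[lo:hi][inside] +
      amps[p] * 0.5 * (1 + cos(pi * d[inside] / h))
  }
  m
}

envelope_to_recording <- function(m, fs, start_time, range_g, noise_sd_g,
                                  label) {
  m <- pmax(m, 0)  # magnitude envelope cannot be negative
  xyz <- m %o% GAIT_AXIS
  if (noise_sd_g > 0) {
    xyz <- xyz + stats::rnorm(length(xyz), 0, noise_sd_g)
  }
  xyz[xyz > range_g] <- range_g
  xyz[xyz < -range_g] <- -range_g
  raw_recording(xyz, start_time, fs, range_g, label)
}

#' Simulate one gait bout
#'
#' Generates a wrist recording of a single stepping bout: 1 g baseline plus
#' one raised-cosine pulse per step at the programmed cadence (peak
#' `1 + swing_amplitude_g`), optional second-harmonic content and phase
#' jitter, distributed across the axes by a fixed rotation, with optional
#' additive Gaussian axis noise. The exact programmed step times are
#' returned alongside the recording.
#'
#' @param spec a [gait_bout()].
#' @param device list with `sample_rate_hz` and `dynamic_range_g` (default:
#'   100 Hz, +/-8 g wrist device).
#' @param noise_sd_g additive Gaussian axis noise SD in g (default 0).
#' @param start_time recording start timestamp.
#' @param seed optional integer seed (restores the caller's RNG state).
#' @return list with `recording` ([raw_recording()]) and `step_times`
#'   (seconds from recording start).
#' @export
simulate_bout <- function(spec,
                          device = list(sample_rate_hz = 100,
                                        dynamic_range_g = 8),
                          noise_sd_g = 0,
                          start_time = "2022-06-01 12:00:00",
                          seed = NULL) {
  stopifnot(inherits(spec, "gait_bout"))
  if (1 + spec$swing_amplitude_g > device$dynamic_range_g) {
    stop("swing amplitude exceeds the device dynamic range (clipping)")
  }
  with_seed(seed, {
    fs <- device$sample_rate_hz
    n <- round(spec$duration_s * fs)
    pulses <- bout_pulses(spec)
    m <- add_pulses(rep(1, n), fs, pulses$time_s, pulses$amp,
                    pulses$half_width)
    rec <- envelope_to_recording(m, fs, start_time, device$dynamic_range_g,
                                 noise_sd_g, "simulated-wrist")
    list(recording = rec, step_times = pulses$time_s[pulses$is_step])
  })
}

#' Simulate non-step arm-movement artefacts
#'
#' Draws isolated bursts of aperiodic high-amplitude wrist movement (the
#' kind produced by washing dishes or typing, a known source of wrist
#' step-count false positives). Burst onsets are Poisson over the span; each
#' burst contains 3-8 peaks with irregular inter-peak gaps and random
#' heights, and contains zero true steps by construction.
#'
#' @param span_s time span covered, seconds.
#' @param rate_per_hour expected bursts per hour (>= 0).
#' @param amplitude_g maximum peak amplitude above baseline, in g.
#' @param seed optional integer seed.
#' @return data.frame of artefact pulses: `time_s`, `amp`, `half_width`.
#' @export
simulate_artefacts <- function(span_s, rate_per_hour, amplitude_g = 1.4,
                               seed = NULL) {
  if (rate_per_hour < 0) stop("rate_per_hour must be >= 0")
  empty <- data.frame(time_s = numeric(0), amp = numeric(0),
                      half_width = numeric(0))
  if (rate_per_hour == 0) return(empty)
  with_seed(seed, {
    n_burst <- stats::rpois(1, rate_per_hour * span_s / 3600)
    if (n_burst == 0) return(empty)
    onsets <- sort(stats::runif(n_burst, 0, max(span_s - 10, 0)))
    out <- lapply(onsets, function(t0) {
      n_pk <- sample(3:8, 1)
      gaps <- stats::runif(n_pk, 0.15, 0.9)  # irregular, non-periodic
      data.frame(
        time_s = t0 + cumsum(gaps),
        amp = stats::runif(n_pk, 0.4, 1) * amplitude_g,
        half_width = stats::runif(n_pk, 0.05, 0.15)
      )
    })
    out <- do.call(rbind, out)
    out[out$time_s < span_s - 1, , drop = FALSE]
  })
}

#' Day scenario for the simulator
#'
#' A full synthetic day: an ordered set of non-overlapping gait bouts on a
#' resting 1 g baseline, plus Poisson arm-movement artefact bursts and
#' additive Gaussian sensor noise, recorded by a wrist device model.
#'
#' @param bouts list of [gait_bout()] objects with `start_offset_s` set;
#'   must not overlap and must fit inside `duration_s`.
#' @param artefact_rate_per_hour expected artefact bursts per hour
#'   (default 20, a busy free-living hand).
#' @param artefact_amplitude_g artefact peak amplitude bound (default 1.4 g).
#' @param noise_sd_g sensor noise SD (default 0.01 g, i.e. 10 mg).
#' @param device wrist device model (default 100 Hz, +/-8 g).
#' @param seed integer seed; every random element of the day flows from it.
#' @param start_date calendar date of the day (midnight anchor).
#' @param duration_s total span, at most 24 h (default 86400).
#' @return object of class `day_scenario`.
#' @export
day_scenario <- function(bouts = list(),
                         artefact_rate_per_hour = 20,
                         artefact_amplitude_g = 1.4,
                         noise_sd_g = 0.01,
                         device = list(sample_rate_hz = 100,
                                       dynamic_range_g = 8),
                         seed = 1,
                         start_date = "2022-06-01",
                         duration_s = 86400) {
  if (duration_s <= 0 || duration_s > 86400) {
    stop("duration_s must be in (0, 86400]")
  }
  if (length(bouts)) {
    off <- vapply(bouts, `[[`, numeric(1), "start_offset_s")
    bouts <- bouts[order(off)]
    off <- sort(off)
    ends <- off + vapply(bouts, `[[`, numeric(1), "duration_s")
    if (any(ends > duration_s) || any(off < 0)) {
      stop("bout extends outside the day span")
    }
    if (length(bouts) > 1L && any(off[-1] < ends[-length(ends)])) {
      stop("overlapping bouts")
    }
  }
  structure(
    list(bouts = bouts, artefact_rate_per_hour = artefact_rate_per_hour,
         artefact_amplitude_g = artefact_amplitude_g,
         noise_sd_g = noise_sd_g, device = device, seed = as.integer(seed),
         start_date = as.Date(start_date), duration_s = duration_s),
    class = "day_scenario"
  )
}

#' Simulate a full day with ground truth
#'
#' Builds the day's magnitude envelope (rest baseline, gait-bout pulse
#' trains, artefact bursts), converts it to a tri-axial recording with
#' sensor noise, and returns it together with the exact ground truth.
#' Deterministic for a fixed scenario seed: identical scenarios give
#' byte-identical recordings.
#'
#' @param scenario a [day_scenario()].
#' @param mvpa_cadence_spm cadence at or above which a bout's steps count as
#'   MVPA in the ground truth (default 100).
#' @return list with `recording` ([raw_recording()]) and `truth`, a list
#'   holding `step_times` (POSIXct), `step_cadence_spm` (the programmed
#'   cadence of each step's bout), `daily_total`, `daily_mvpa`, and `date`.
#' @export
simulate_day <- function(scenario, mvpa_cadence_spm = 100) {
  stopifnot(inherits(scenario, "day_scenario"))
  with_seed(scenario$seed, {
    fs <- scenario$device$sample_rate_hz
    n <- round(scenario$duration_s * fs)
    start_time <- as_naive_time(paste(scenario$start_date, "00:00:00"))

    pulse_tabs <- lapply(scenario$bouts, function(b) {
      p <- bout_pulses(b)
      p$time_s <- p$time_s + b$start_offset_s
      p$cadence <- b$cadence_spm
      p
    })
    art <- simulate_artefacts(scenario$duration_s,
                              scenario$artefact_rate_per_hour,
                              scenario$artefact_amplitude_g)
    m <- rep(1, n)
    for (p in pulse_tabs) {
      m <- add_pulses(m, fs, p$time_s, p$amp, p$half_width)
    }
    if (nrow(art)) {
      m <- add_pulses(m, fs, art$time_s, art$amp, art$half_width)
    }
    rec <- envelope_to_recording(m, fs, start_time,
                                 scenario$device$dynamic_range_g,
                                 scenario$noise_sd_g, "simulated-wrist")

    steps <- do.call(rbind, c(
      list(data.frame(time_s = numeric(0), cadence = numeric(0))),
      lapply(pulse_tabs, function(p) {
        p[p$is_step, c("time_s", "cadence")]
      })
    ))
    steps <- steps[order(steps$time_s), , drop = FALSE]
    truth <- list(
      step_times = start_time + steps$time_s,
      step_cadence_spm = steps$cadence,
      daily_total = nrow(steps),
      daily_mvpa = sum(steps$cadence >= mvpa_cadence_spm),
      date = scenario$start_date
    )
    list(recording = rec, truth = truth)
  })
}

#' Emulated thigh-worn reference device
#'
#' Converts the simulator's ground truth into the daily summary a thigh-worn
#' comparator would report: steps from bouts below a cadence floor are not
#' detected (the comparator's known slow-walking blind spot, default 40
#' steps/min), and each remaining step is independently missed with
#' probability `random_miss_rate`.
#'
#' @param truth the `truth` element of [simulate_day()] output.
#' @param miss_below_cadence_spm cadence floor in steps/min (default 40).
#' @param random_miss_rate per-step miss probability in [0, 1] (default 0.02).
#' @param mvpa_cadence_spm MVPA cadence threshold (default 100).
#' @param seed optional integer seed.
#' @return a [daily_summary()] row for the reference device.
#' @export
simulate_reference_device <- function(truth, miss_below_cadence_spm = 40,
                                      random_miss_rate = 0.02,
                                      mvpa_cadence_spm = 100, seed = NULL) {
  if (random_miss_rate < 0 || random_miss_rate > 1) {
    stop("random_miss_rate must lie in [0, 1]")
  }
  with_seed(seed, {
    eligible <- truth$step_cadence_spm >= miss_below_cadence_spm
    detected <- eligible
    if (random_miss_rate > 0 && any(eligible)) {
      detected[eligible] <-
        stats::runif(sum(eligible)) >= random_miss_rate
    }
    daily_summary(
      date = truth$date,
      total_steps = sum(detected),
      mvpa_steps = sum(detected & truth$step_cadence_spm >= mvpa_cadence_spm),
      wear_complete = TRUE, qc_pass = TRUE
    )
  })
}

#' A realistic built-in day scenario
#'
#' A free-living office-worker day used by the examples and the acceptance
#' harness: a brisk morning walk, a lunchtime stroll, short ambling bouts,
#' an evening run, plus background artefacts and sensor noise. Roughly
#' 10,000 programmed steps of which the brisk/running bouts are MVPA.
#'
#' @param seed scenario seed.
#' @param duration_s day length in seconds (default 24 h).
#' @return a [day_scenario()].
#' @export
example_day_scenario <- function(seed = 7, duration_s = 86400) {
  day_scenario(
    bouts = list(
      gait_bout(115, 1800, 0.60, start_offset_s = 7.5 * 3600),  # commute walk
      gait_bout(85, 600, 0.45, start_offset_s = 10.5 * 3600),   # coffee amble
      gait_bout(105, 900, 0.55, start_offset_s = 12.5 * 3600),  # lunch stroll
      gait_bout(80, 480, 0.45, start_offset_s = 15.0 * 3600),   # corridor
      gait_bout(160, 1200, 0.90, start_offset_s = 18.0 * 3600), # evening run
      gait_bout(95, 600, 0.50, start_offset_s = 20.5 * 3600)    # dog walk
    ),
    artefact_rate_per_hour = 20,
    artefact_amplitude_g = 1.4,
    noise_sd_g = 0.01,
    seed = seed,
    duration_s = duration_s
  )
}
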