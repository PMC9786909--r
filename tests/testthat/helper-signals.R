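# Shared fixture builders. Everything is generated in code; no stored data.

T0 <- "2022-06-01 00:00:00"

# A constant-orientation recording with optional axis jitter.
still_recording <- function(n = 1000, fs = 100, jitter_sd = 0,
                            start = T0) {
  xyz <- matrix(c(rep(0, 2 * n), rep(1, n)), ncol = 3)
  if (jitter_sd > 0) xyz <- xyz + matrix(rnorm(3 * n, 0, jitter_sd), ncol = 3)
  raw_recording(xyz, start, fs)
}

# Varied random signals at the algorithm rate (15 Hz) used for the
# oracle-equivalence and monotone-filtering properties: mixtures of rest,
# broadband noise and oscillatory segments so every filter stage gets
# exercised.
random_signal <- function(seed, n = 1000, fs = 15) {
  set.seed(seed)
  m <- rep(1, n)
  n_seg <- sample(2:6, 1)
  bounds <- sort(sample(seq_len(n - 1), n_seg - 1))
  starts <- c(1, bounds + 1)
  ends <- c(bounds, n)
  for (s in seq_len(n_seg)) {
    idx <- starts[s]:ends[s]
    kind <- sample(c("rest", "noise", "osc"), 1)
    if (kind == "noise") {
      m[idx] <- m[idx] + rnorm(length(idx), 0, runif(1, 0.05, 0.5))
    } else if (kind == "osc") {
      f <- runif(1, 1, 3)  # step-band oscillation
      amp <- runif(1, 0.2, 1.2)
      m[idx] <- m[idx] + amp * sin(2 * pi * f * (idx - idx[1]) / fs) +
        rnorm(length(idx), 0, 0.05)
    } else {
      m[idx] <- m[idx] + rnorm(length(idx), 0, 0.003)
    }
  }
  m <- pmax(m, 0)
  # distribute over axes with a unit vector so the norm equals m exactly
  raw_recording(m %o% (c(2, 1, 2) / 3), T0, fs)
}

# Peak-set signature of a step_events object for exact comparisons.
event_times_s <- function(ev, origin = T0) {
  as.numeric(ev$times) - as.numeric(stepsense:::as_naive_time(origin))
}

expect_same_events <- function(a, b) {
  expect_equal(as.numeric(a$times), as.numeric(b$times), tolerance = 1e-9)
}
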