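mag_of <- function(v, fs = 15) magnitude_series(v, T0, fs)

test_that("both shipped presets carry the published thresholds", {
  p1 <- verisense_params("verisense1")
  expect_equal(
    unlist(unclass(p1)[1:8]),
    c(peak_win_samples = 3, min_period_samples = 5, max_period_samples = 15,
      similarity_threshold_g = -0.5, continuity_window_samples = 4,
      continuity_count_threshold = 4, variance_threshold_g2 = 0.001,
      magnitude_threshold_g = 1.2)
  )
  p2 <- verisense_params("verisense2")
  expect_equal(
    unlist(unclass(p2)[1:8]),
    c(peak_win_samples = 4, min_period_samples = 4, max_period_samples = 20,
      similarity_threshold_g = -1.0, continuity_window_samples = 4,
      continuity_count_threshold = 4, variance_threshold_g2 = 0.01,
      magnitude_threshold_g = 1.25)
  )
  expect_error(step_parameters(min_period_samples = 10,
                               max_period_samples = 5), "exceed")
  expect_error(step_parameters(similarity_threshold_g = 0.5), "<= 0")
})

test_that("candidate peaks are strict local maxima away from the edges", {
  # exhaustive-scan example: single interior strict max
  pk <- find_candidate_peaks(mag_of(c(1, 1, 2, 1, 1)), 2)
  expect_equal(pk$indices, 3L)
  expect_equal(pk$heights_g, 2)

  # monotone series has no interior strict max
  expect_equal(length(find_candidate_peaks(mag_of(seq(0, 2, length = 30)),
                                           3)), 0L)

  # adjacent equal-height maxima (plateau): strictness yields no candidate
  expect_equal(length(find_candidate_peaks(
    mag_of(c(1, 1, 2, 2, 1, 1, 1)), 2)), 0L)

  # edge exclusion: a max within k of either end is not a candidate
  expect_equal(length(find_candidate_peaks(mag_of(c(5, 1, 1, 1, 5)), 2)), 0L)

  expect_warning(pk0 <- find_candidate_peaks(mag_of(c(1, 2, 1)), 2), "short")
  expect_equal(length(pk0), 0L)

  # exhaustive scan oracle on a random trace
  set.seed(11)
  v <- runif(200, 0.8, 2)
  k <- 3L
  oracle <- integer(0)
  for (i in (k + 1L):(200L - k)) {
    if (all(v[i] > v[setdiff((i - k):(i + k), i)])) oracle <- c(oracle, i)
  }
  expect_equal(find_candidate_peaks(mag_of(v), k)$indices, oracle)
})

test_that("magnitude filter applies the preset thresholds", {
  pk <- peak_list(c(10L, 20L), c(1.1, 1.3))
  kept <- filter_magnitude(pk, 1.2)
  expect_equal(kept$indices, 20L)
  expect_equal(kept$heights_g, 1.3)
  expect_equal(length(filter_magnitude(peak_list(), 1.2)), 0L)
  expect_equal(filter_magnitude(pk, 0)$indices, pk$indices)
})

test_that("periodicity filter implements the closed-interval gap chain", {
  # peaks every 10 samples in window [5, 15]: all retained
  pk <- peak_list(seq(10L, 100L, by = 10L), rep(1.5, 10))
  expect_equal(filter_periodicity(pk, 5, 15)$indices, pk$indices)

  # peaks every 16 samples: all removed under the original preset (max 15)
  # but retained under the refined preset (max 20)
  pk16 <- peak_list(seq(16L, 160L, by = 16L), rep(1.5, 10))
  expect_equal(length(filter_periodicity(pk16, 5, 15)), 0L)
  expect_equal(filter_periodicity(pk16, 4, 20)$indices, pk16$indices)

  # a single isolated peak has no compliant neighbour
  expect_equal(length(filter_periodicity(peak_list(5L, 1.5), 4, 20)), 0L)

  # a too-close intruder is dropped without breaking the chain
  pk <- peak_list(c(10L, 20L, 22L, 30L), rep(1.5, 4))
  expect_equal(filter_periodicity(pk, 5, 15)$indices, c(10L, 20L, 30L))

  # a long gap reseeds: trailing pair retained, isolated head dropped
  pk <- peak_list(c(10L, 100L, 110L), rep(1.5, 3))
  expect_equal(filter_periodicity(pk, 5, 15)$indices, c(100L, 110L))
})

test_that("similarity filter compares consecutive heights to -|threshold|", {
  eq <- peak_list(c(1L, 10L, 20L), rep(1.4, 3))
  expect_equal(filter_similarity(eq, -0.5)$indices, eq$indices)

  alt <- peak_list(seq(10L, 60L, by = 10L), rep(c(1.3, 2.5), 3))
  expect_equal(length(filter_similarity(alt, -0.5)), 0L)  # |d| = 1.2 > 0.5
  expect_equal(length(filter_similarity(alt, -1.0)), 0L)  # still > 1.0

  alt2 <- peak_list(seq(10L, 60L, by = 10L), rep(c(1.3, 2.0), 3))
  expect_equal(length(filter_similarity(alt2, -0.5)), 0L)     # 0.7 > 0.5
  expect_equal(filter_similarity(alt2, -1.0)$indices, alt2$indices)

  # boundary: |d| exactly equal to |threshold| is similar
  pair <- peak_list(c(1L, 5L), c(1.0, 1.5))
  expect_equal(filter_similarity(pair, -0.5)$indices, pair$indices)

  expect_equal(length(filter_similarity(peak_list(3L, 1.5), -1.0)), 0L)
})

test_that("continuity filter requires surrounding motion windows", {
  # constant signal: variance 0 everywhere, all peaks removed
  m <- mag_of(rep(1, 200))
  pk <- peak_list(c(50L, 100L), c(1, 1))
  expect_equal(length(filter_continuity(pk, m, 4, 4, 0.01)), 0L)

  # a lone spike in a still trace: its neighbours are all below threshold
  v <- rep(1, 200); v[100] <- 3
  pk <- peak_list(100L, 3)
  expect_equal(length(filter_continuity(pk, mag_of(v), 4, 4, 0.01)), 0L)

  # naive window-variance loop oracle retains the identical peak set
  set.seed(5)
  v <- 1 + rnorm(400, 0, 0.2) * rep(rep(c(0, 1), each = 40), 5)
  mg <- mag_of(pmax(v, 0))
  pk <- find_candidate_peaks(mg, 3)
  got <- filter_continuity(pk, mg, 4, 4, 0.01)
  w <- 4L; cth <- 4L; n_win <- length(mg$values_g) %/% w
  motion <- logical(n_win)
  for (wi in seq_len(n_win)) {
    seg <- mg$values_g[((wi - 1) * w + 1):(wi * w)]
    motion[wi] <- mean((seg - mean(seg))^2) > 0.01
  }
  keep <- vapply(pk$indices, function(i) {
    wi <- (i - 1L) %/% w + 1L
    nb <- wi + c(-(cth:1), 1:cth)
    sum(motion[nb[nb >= 1 & nb <= n_win]]) >= cth
  }, logical(1))
  expect_equal(got$indices, pk$indices[keep])
})

test_that("count_steps rejects rest and recovers clean gait", {
  p1 <- verisense_params("verisense1")
  p2 <- verisense_params("verisense2")

  set.seed(1)
  still <- still_recording(n = 6000, fs = 100, jitter_sd = 0.002)
  expect_equal(length(count_steps(still, p1)), 0L)
  expect_equal(length(count_steps(still, p2)), 0L)

  # 10 s of noise-free gait at 120 steps/min, swing high enough for 1.25 g
  b <- simulate_bout(gait_bout(120, 10, 0.8, phase_jitter_sd = 0), seed = 2)
  expect_equal(length(b$step_times), 20L)
  got <- count_steps(b$recording, p2)
  expect_same_events(got, naive_count_steps(b$recording, p2))
  expect_lte(abs(length(got) - 20L), 2L)

  # both presets run on the same trace and give nearby counts
  got1 <- count_steps(b$recording, p1)
  expect_true(length(got1) > 0)
})

test_that("filtering is monotone and deterministic", {
  p2 <- verisense_params("verisense2")
  for (seed in 1:15) {
    r <- random_signal(seed)
    mag <- vector_magnitude(r)
    a <- suppressWarnings(find_candidate_peaks(mag, p2$peak_win_samples))
    b <- filter_magnitude(a, p2$magnitude_threshold_g)
    c_ <- filter_periodicity(b, p2$min_period_samples, p2$max_period_samples)
    d <- filter_similarity(c_, p2$similarity_threshold_g)
    e <- filter_continuity(d, mag, p2$continuity_window_samples,
                           p2$continuity_count_threshold,
                           p2$variance_threshold_g2)
    expect_true(length(a) >= length(b) && length(b) >= length(c_) &&
                  length(c_) >= length(d) && length(d) >= length(e))
  }
  b <- simulate_bout(gait_bout(100, 20, 0.6), noise_sd_g = 0.02, seed = 9)
  expect_same_events(count_steps(b$recording), count_steps(b$recording))
})

test_that("chunk-and-sum counting stays within 2 steps per split point", {
  p2 <- verisense_params("verisense2")
  for (seed in c(3, 8, 21)) {
    b <- simulate_bout(gait_bout(115, 60, 0.6), noise_sd_g = 0.02,
                       seed = seed)
    whole <- length(count_steps(b$recording, p2))
    n_half <- 3000L  # split at the 30 s epoch boundary (100 Hz)
    first <- raw_recording(b$recording$xyz[1:n_half, ], T0, 100)
    second <- raw_recording(b$recording$xyz[(n_half + 1):6000, ], T0, 100)
    split_sum <- length(count_steps(first, p2)) +
      length(count_steps(second, p2))
    expect_lte(abs(whole - split_sum), 2L)
  }
})

test_that("count_steps warns and returns zero events on too-short input", {
  p2 <- verisense_params("verisense2")
  tiny <- still_recording(n = 3, fs = 15)
  expect_warning(ev <- count_steps(tiny, p2), "short")
  expect_equal(length(ev), 0L)
  expect_error(count_steps(still_recording(n = 0), p2), "empty")
})
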