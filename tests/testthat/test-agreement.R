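test_that("bland_altman matches hand-computed closed forms", {
  # identical series: zero bias, collapsed LoA, degenerate flag
  expect_warning(ba <- bland_altman(c(5, 6, 7), c(5, 6, 7)), "zero variance")
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa, c(0, 0))
  expect_true(ba$degenerate)

  # differences {1, 2, 3}: bias 2, sd 1, LoA 2 -/+ 1.96
  ba <- bland_altman(c(2, 3, 4), c(1, 1, 1))
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa, c(0.04, 3.96))
  # CI from the t distribution with n - 1 df
  expect_equal(ba$bias_ci,
               2 + c(-1, 1) * qt(0.975, 2) * 1 / sqrt(3))

  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("Bland-Altman invariants hold on random pairs", {
  set.seed(99)
  for (i in 1:10) {
    x <- rnorm(30, 10000, 2000)
    y <- x + rnorm(30, 500, 800)
    ba <- bland_altman(y, x)
    expect_equal(mean(ba$loa), ba$bias, tolerance = 1e-9)
    expect_equal(diff(ba$loa), 2 * 1.96 * ba$sd_diff)
    expect_lte(ba$bias_ci[1], ba$bias)
    expect_gte(ba$bias_ci[2], ba$bias)
    # swapping test and reference negates the bias and mirrors the LoA
    sw <- bland_altman(x, y)
    expect_equal(sw$bias, -ba$bias)
    expect_equal(sw$loa, -rev(ba$loa))
    expect_equal(suppressWarnings(bland_altman(x, x))$bias, 0)
  }
})

test_that("proportional bias recovers known slopes", {
  # constant difference: slope 0, intercept c, CI covers 0
  m <- seq(2000, 15000, length.out = 40)
  pb <- suppressWarnings(proportional_bias(m + 250, m - 250))
  expect_equal(pb$slope, 0, tolerance = 1e-12)
  expect_equal(pb$intercept, 500, tolerance = 1e-9)
  expect_true(pb$no_proportional_bias)

  # difference independent of mean, with noise: CI covers 0
  set.seed(21)
  d <- rnorm(60, 100, 30)
  base <- seq(3000, 12000, length.out = 60)
  pb <- proportional_bias(base + d / 2, base - d / 2)
  expect_true(pb$slope_ci[1] <= 0 && 0 <= pb$slope_ci[2])

  # parameter recovery: difference = 100 - 0.05 * mean + N(0, 1)
  set.seed(42)
  mean_ax <- seq(4000, 14000, length.out = 80)
  diff_ax <- 100 - 0.05 * mean_ax + rnorm(80, 0, 1)
  test <- mean_ax + diff_ax / 2
  ref <- mean_ax - diff_ax / 2
  pb <- proportional_bias(test, ref)
  expect_true(pb$slope_ci[1] <= -0.05 && -0.05 <= pb$slope_ci[2])
  expect_false(pb$no_proportional_bias)

  expect_error(proportional_bias(c(5, 5, 5), c(3, 3, 3)), "degenerate")
})

test_that("MAPE and percent bias follow their closed forms", {
  expect_equal(mape(c(100, 200), c(100, 200)), 0)
  expect_equal(mape(c(110, 90), c(100, 100)), 10)
  ref <- c(5000, 8000, 11000)
  expect_equal(mape(1.2 * ref, ref), 20, tolerance = 1e-12)
  expect_error(mape(c(1, 2), c(1, 0)), "pair\\(s\\) 2")

  expect_equal(round_half_up(percent_bias(742, 9352.2), 1), 7.9)
  expect_equal(percent_bias(0, 1234), 0)
  expect_equal(percent_bias(-350, 7000), -percent_bias(350, 7000))
  expect_error(percent_bias(100, 0), "positive")

  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.345, 1), 2.3)
  expect_equal(round_half_up(912.8), 913)
})

test_that("agreement_analysis supports participant- and day-level pairing", {
  pairs <- data.frame(
    date = as.Date("2022-06-01") + 0:4,
    participant = c("a", "a", "a", "b", "b"),
    wrist_total = c(10000, 11000, 12000, 8000, 9000),
    reference_total = c(9000, 10000, 11000, 8500, 9500),
    wrist_mvpa = c(3000, 3100, 3200, 2000, 2100),
    reference_mvpa = c(4000, 4100, 4200, 2500, 2600)
  )
  by_day <- agreement_analysis(pairs, "total", unit = "day")
  expect_equal(by_day$n_pairs, 5L)
  expect_equal(by_day$bias, mean(pairs$wrist_total - pairs$reference_total))

  by_part <- agreement_analysis(pairs, "total")  # participant default
  expect_equal(by_part$n_pairs, 2L)
  # hand computation: participant means a: +1000, b: -500 -> bias 250
  expect_equal(by_part$bias, 250)
  expect_equal(by_part$unit, "participant")

  # without a participant column the participant default degrades to rows
  expect_equal(agreement_analysis(pairs[, -2], "total")$n_pairs, 5L)
})

test_that("tuning selects by |mean bias| with documented tie-breaking", {
  p2 <- verisense_params("verisense2")

  # training set: three clean bouts whose swing keeps sampled peaks between
  # 1.25 and 1.5 g, so threshold 1.25 detects nearly all programmed steps
  # and threshold 1.5 detects none
  train <- lapply(c(1, 2, 3), function(s) {
    simulate_bout(gait_bout(c(100, 110, 120)[s], 60, 0.4), seed = s)
  })
  recs <- lapply(train, `[[`, "recording")
  refs <- vapply(train, function(x) length(x$step_times), numeric(1))

  # singleton grid returns its element
  single <- tune_parameters(list(magnitude_threshold_g = 1.25), recs, refs)
  expect_equal(single$n_combos, 1L)
  expect_equal(single$selected$magnitude_threshold_g, 1.25)

  # two-point magnitude grid selects the low-bias threshold
  two <- tune_parameters(list(magnitude_threshold_g = c(1.5, 1.25)),
                         recs, refs)
  expect_equal(two$n_combos, 2L)
  expect_equal(two$selected$magnitude_threshold_g, 1.25)
  # and the direct bias computation confirms the separation
  s <- two$scores
  expect_lt(s$abs_mean_bias[s$magnitude_threshold_g == 1.25],
            s$abs_mean_bias[s$magnitude_threshold_g == 1.5])

  # determinism given grid order and data
  again <- tune_parameters(list(magnitude_threshold_g = c(1.5, 1.25)),
                           recs, refs)
  expect_identical(two$scores, again$scores)

  # infeasible combinations are skipped with a log message
  expect_message(
    mix <- tune_parameters(
      list(min_period_samples = c(4, 25), max_period_samples = c(15, 20)),
      recs[1], refs[1]
    ),
    "infeasible"
  )
  expect_equal(mix$n_combos, 2L)  # 4 raw combos, 2 with min 25 > max

  expect_error(tune_parameters(list(), recs, refs), "empty")
  expect_error(tune_parameters(list(bogus = 1), recs, refs), "unknown")
})
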