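#' Bland-Altman agreement analysis
#'
#' Computes, for paired measurements of the same quantity by a test and a
#' reference method: mean bias (test minus reference), its confidence
#' interval from the t distribution (`bias +/- t(n-1, level) * sd / sqrt(n)`),
#' the sample standard deviation of the differences (divisor n-1), and 95%
#' limits of agreement `bias +/- 1.96 * sd`. The LoA multiplier is fixed at
#' 1.96 by convention. With zero-variance differences the LoA collapse to
#' `(bias, bias)` and the result is flagged.
#'
#' @param test,reference numeric vectors of paired measurements; or pass a
#'   two-column object (test, reference) as `test` alone.
#' @param level confidence level for the CI of the bias (default 0.95).
#' @return An object of class `bland_altman` (list): `n_pairs`, `bias`,
#'   `bias_ci` (low, high), `sd_diff`, `loa` (low, high), `level`,
#'   `degenerate` (logical, zero-variance flag).
#' @examples
#' ba <- bland_altman(c(2, 3, 4), c(1, 1, 1))  # differences 1, 2, 3
#' ba$bias  # 2
#' ba$loa   # c(0.04, 3.96)
#' @export
bland_altman <- function(test, reference = NULL, level = 0.95) {
  if (is.null(reference)) {
    test <- as.matrix(test)
    reference <- as.numeric(test[, 2L])
    test <- as.numeric(test[, 1L])
  }
  if (length(test) != length(reference)) stop("unequal pair lengths")
  n <- length(test)
  if (n < 2L) stop("Bland-Altman analysis needs at least 2 pairs")
  d <- test - reference
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  degenerate <- sd_diff == 0
  if (degenerate) {
    warning("zero variance of differences; limits of agreement collapse")
  }
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  se <- sd_diff / sqrt(n)
  structure(
    list(
      n_pairs = n,
      bias = bias,
      bias_ci = c(bias - tq * se, bias + tq * se),
      sd_diff = sd_diff,
      loa = c(bias - 1.96 * sd_diff, bias + 1.96 * sd_diff),
      level = level,
      degenerate = degenerate
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.2f (%.0f%% CI %.2f, %.2f); LoA %.2f, %.2f\n",
    x$n_pairs, x$bias, 100 * x$level, x$bias_ci[1], x$bias_ci[2],
    x$loa[1], x$loa[2]
  ))
  invisible(x)
}

#' Proportional bias of paired measurements
#'
#' Ordinary least-squares regression of the paired difference
#' (test - reference) on the paired mean (test + reference) / 2. A non-zero
#' slope indicates that the between-method difference depends on the
#' magnitude being measured; "no proportional bias" is declared iff the
#' slope's confidence interval covers 0.
#'
#' @inheritParams bland_altman
#' @return list with `slope`, `intercept`, `slope_ci` (low, high), `level`,
#'   and `no_proportional_bias` (logical).
#' @export
proportional_bias <- function(test, reference = NULL, level = 0.95) {
  if (is.null(reference)) {
    test <- as.matrix(test)
    reference <- as.numeric(test[, 2L])
    test <- as.numeric(test[, 1L])
  }
  if (length(test) < 3L) stop("proportional bias needs at least 3 pairs")
  d <- test - reference
  m <- (test + reference) / 2
  if (stats::sd(m) == 0) stop("degenerate pairs: all means identical")
  fit <- stats::lm(d ~ m)
  ci <- stats::confint(fit, "m", level = level)
  slope <- unname(stats::coef(fit)["m"])
  list(
    slope = slope,
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    slope_ci = c(ci[1L], ci[2L]),
    level = level,
    no_proportional_bias = ci[1L] <= 0 && 0 <= ci[2L]
  )
}

#' Mean absolute percent error
#'
#' `mean(|test - reference| / reference) * 100` over pairs; every reference
#' value must be strictly positive.
#'
#' @inheritParams bland_altman
#' @return MAPE in percent.
#' @export
mape <- function(test, reference = NULL) {
  if (is.null(reference)) {
    test <- as.matrix(test)
    reference <- as.numeric(test[, 2L])
    test <- as.numeric(test[, 1L])
  }
  bad <- which(reference <= 0)
  if (length(bad)) {
    stop("non-positive reference value in pair(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  mean(abs(test - reference) / reference) * 100
}

#' Bias as a percentage of the reference mean
#'
#' @param bias mean bias (test minus reference), in measurement units.
#' @param reference_mean positive mean of the reference method.
#' @return `bias / reference_mean * 100` (unrounded; display convention is
#'   1 decimal place, see [round_half_up()]).
#' @examples
#' round_half_up(percent_bias(742, 9352.2), 1)  # 7.9
#' @export
percent_bias <- function(bias, reference_mean) {
  if (reference_mean <= 0) stop("reference_mean must be positive")
  bias / reference_mean * 100
}

#' Half-away-from-zero display rounding
#'
#' Display convention for reported numbers: biases to integers, percentages
#' to 1 decimal place, halves rounded away from zero (unlike base R's
#' round-half-even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Full agreement summary for paired daily steps
#'
#' Convenience wrapper combining [bland_altman()], [proportional_bias()] and
#' [mape()] into one `agreement_result` for a metric of a paired-day table.
#'
#' @param pairs a `paired_daily` data.frame from [pair_days()], optionally
#'   with a `participant` column.
#' @param metric `"total"` or `"mvpa"`.
#' @param level confidence level.
#' @param unit pairing unit: `"participant"` (default — each participant's
#'   valid days are averaged first, giving one pair per participant;
#'   requires a `participant` column, otherwise every row is its own pair)
#'   or `"day"` (one pair per valid day, days weighted equally).
#' @return list of class `agreement_result` with fields `metric`, `unit`,
#'   `n_pairs`, `bias`, `bias_ci`, `sd_diff`, `loa`, `prop_slope`,
#'   `prop_slope_ci`, `mape_pct`, `percent_bias`.
#' @export
agreement_analysis <- function(pairs, metric = c("total", "mvpa"),
                               level = 0.95,
                               unit = c("participant", "day")) {
  metric <- match.arg(metric)
  unit <- match.arg(unit)
  if (unit == "participant" && "participant" %in% names(pairs)) {
    pairs <- stats::aggregate(
      pairs[, c(paste0("wrist_", metric), paste0("reference_", metric))],
      by = list(participant = pairs$participant), FUN = mean
    )
  }
  test <- pairs[[paste0("wrist_", metric)]]
  ref <- pairs[[paste0("reference_", metric)]]
  ba <- bland_altman(test, ref, level)
  pb <- if (length(test) >= 3L && stats::sd((test + ref) / 2) > 0) {
    proportional_bias(test, ref, level)
  } else {
    list(slope = NA_real_, slope_ci = c(NA_real_, NA_real_))
  }
  mp <- if (all(ref > 0)) mape(test, ref) else NA_real_
  pc <- if (mean(ref) > 0) percent_bias(ba$bias, mean(ref)) else NA_real_
  structure(
    list(metric = metric, unit = unit, n_pairs = ba$n_pairs, bias = ba$bias,
         bias_ci = ba$bias_ci, sd_diff = ba$sd_diff, loa = ba$loa,
         prop_slope = pb$slope, prop_slope_ci = pb$slope_ci,
         mape_pct = mp, percent_bias = pc, level = level),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    paste0("Agreement (%s steps, n = %d days):\n",
           "  bias %+d steps/day (CI %.0f, %.0f); LoA %.0f, %.0f\n",
           "  proportional-bias slope %.4f (CI %.4f, %.4f)\n",
           "  MAPE %.1f%%; percent bias %+.1f%%\n"),
    x$metric, x$n_pairs, round_half_up(x$bias), x$bias_ci[1], x$bias_ci[2],
    x$loa[1], x$loa[2], x$prop_slope, x$prop_slope_ci[1], x$prop_slope_ci[2],
    round_half_up(x$mape_pct, 1), round_half_up(x$percent_bias, 1)
  ))
  invisible(x)
}

#' Exhaustive parameter-grid tuning
#'
#' Evaluates the full Cartesian product of candidate threshold values: for
#' every combination, runs the step counter on every recording and scores
#' the daily bias against the supplied reference totals. The default
#' objective is lexicographic: smallest `|mean bias|`, ties broken by the
#' better balance between over- and under-estimated recordings
#' (`|n_over - n_under|`), remaining ties by grid order. Combinations with
#' `min_period_samples > max_period_samples` are infeasible and skipped (a
#' message is emitted). Deterministic given grid order and data.
#'
#' @param grid_spec named list of candidate vectors for any subset of the
#'   [step_parameters()] fields; unnamed fields take the preset defaults of
#'   `base_params`.
#' @param recordings list of [raw_recording()] objects (the training set).
#' @param reference_steps numeric vector of reference daily/recording step
#'   totals, same length as `recordings`.
#' @param base_params defaults for fields absent from `grid_spec`.
#' @return A `tuning_result`: list with `scores` (data.frame, one row per
#'   feasible combination with its thresholds, `mean_bias`, `abs_mean_bias`,
#'   `n_over`, `n_under`, `balance`), `selected` ([step_parameters()]),
#'   `n_combos`.
#' @export
tune_parameters <- function(grid_spec, recordings, reference_steps,
                            base_params = verisense_params("verisense2")) {
  if (!length(grid_spec)) stop("empty grid specification")
  if (!length(recordings)) stop("no recordings supplied")
  if (length(recordings) != length(reference_steps)) {
    stop("recordings and reference_steps lengths differ")
  }
  fields <- names(unclass(base_params))
  unknown <- setdiff(names(grid_spec), fields)
  if (length(unknown)) stop("unknown parameter fields: ",
                            paste(unknown, collapse = ", "))
  full <- lapply(fields, function(f) {
    if (!is.null(grid_spec[[f]])) grid_spec[[f]] else base_params[[f]]
  })
  names(full) <- fields
  if (length(unique(full$algorithm_rate_hz)) != 1L) {
    stop("algorithm_rate_hz must be a single value across the grid")
  }
  grid <- expand.grid(full, KEEP.OUT.ATTRS = FALSE)
  feasible <- grid$min_period_samples <= grid$max_period_samples
  if (any(!feasible)) {
    message(sum(!feasible), " infeasible combination(s) skipped ",
            "(min period > max period)")
  }
  grid <- grid[feasible, , drop = FALSE]
  if (nrow(grid) == 0L) stop("no feasible combinations in grid")
  rownames(grid) <- NULL

  rate <- full$algorithm_rate_hz[[1L]]
  mags <- lapply(recordings, function(r) {
    mag <- vector_magnitude(r)
    if (mag$sample_rate_hz != rate) mag <- resample_linear(mag, rate)
    mag
  })

  n_combo <- nrow(grid)
  mean_bias <- numeric(n_combo)
  n_over <- integer(n_combo)
  n_under <- integer(n_combo)
  for (i in seq_len(n_combo)) {
    p <- do.call(step_parameters, as.list(grid[i, ]))
    bias <- vapply(seq_along(mags), function(j) {
      length(count_steps_mag(mags[[j]], p)$indices) - reference_steps[j]
    }, numeric(1))
    mean_bias[i] <- mean(bias)
    n_over[i] <- sum(bias > 0)
    n_under[i] <- sum(bias < 0)
  }
  scores <- cbind(
    grid,
    data.frame(mean_bias = mean_bias, abs_mean_bias = abs(mean_bias),
               n_over = n_over, n_under = n_under,
               balance = abs(n_over - n_under))
  )
  best <- order(scores$abs_mean_bias, scores$balance,
                seq_len(n_combo))[1L]
  structure(
    list(
      scores = scores,
      selected = do.call(step_parameters, as.list(grid[best, ])),
      selected_index = best,
      n_combos = n_combo
    ),
    class = "tuning_result"
  )
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %d combinations; best mean bias %+.1f steps\n",
              x$n_combos, x$scores$mean_bias[x$selected_index]))
  print(x$selected)
  invisible(x)
}
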