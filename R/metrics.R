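#' Aggregate step events into fixed epochs
#'
#' Assigns every step event to the half-open epoch `[t, t + epoch_length_s)`
#' containing it; the epoch grid is anchored at the start of `span`. The sum
#' of epoch step counts always equals the number of events. Cadence is
#' derived as `steps * 60 / epoch_length_s` and MVPA flags are set with the
#' default 100 steps/min threshold (re-flag with [classify_mvpa()]).
#'
#' @param events a [step_events()] object.
#' @param epoch_length_s epoch length in seconds (default 5).
#' @param span POSIXct (or parseable) vector of length 2, `c(start, end)`;
#'   must cover every event (`start <= t < end`). The number of epochs is
#'   `ceiling((end - start) / epoch_length_s)`.
#' @return An `epoch_series` data.frame with columns `epoch_start`, `steps`,
#'   `cadence_spm`, `is_mvpa`; attributes `epoch_length_s` and
#'   `mvpa_cadence_spm`.
#' @export
aggregate_epochs <- function(events, epoch_length_s = 5, span) {
  stopifnot(inherits(events, "step_events"), epoch_length_s > 0)
  span <- c(as_naive_time(span[[1]]), as_naive_time(span[[2]]))
  t0 <- as.numeric(span[1]); t1 <- as.numeric(span[2])
  if (t1 <= t0) stop("span end must be after span start")
  tt <- as.numeric(events$times)
  if (length(tt) && (any(tt < t0) || any(tt >= t1))) {
    stop("step events outside the given span")
  }
  n_ep <- ceiling((t1 - t0) / epoch_length_s - 1e-9)
  ep_idx <- floor((tt - t0) / epoch_length_s) + 1L
  steps <- tabulate(ep_idx, nbins = n_ep)
  out <- data.frame(
    epoch_start = span[1] + (seq_len(n_ep) - 1L) * epoch_length_s,
    steps = as.integer(steps),
    cadence_spm = steps * 60 / epoch_length_s,
    is_mvpa = NA
  )
  attr(out, "epoch_length_s") <- epoch_length_s
  class(out) <- c("epoch_series", "data.frame")
  classify_mvpa(out)
}

#' Flag MVPA epochs by cadence
#'
#' An epoch counts as moderate-to-vigorous (MVPA) stepping iff its cadence is
#' at least `mvpa_cadence_spm` (default 100 steps/min — so with 5 s epochs,
#' 9 steps (108 steps/min) is MVPA and 8 steps (96 steps/min) is not).
#' Classification is instantaneous per epoch; no bout detection.
#'
#' @param series an `epoch_series` from [aggregate_epochs()].
#' @param mvpa_cadence_spm cadence threshold in steps/min.
#' @return the series with `is_mvpa` set and the threshold recorded as an
#'   attribute.
#' @export
classify_mvpa <- function(series, mvpa_cadence_spm = 100) {
  stopifnot(inherits(series, "epoch_series"), mvpa_cadence_spm > 0)
  series$is_mvpa <- series$cadence_spm >= mvpa_cadence_spm
  attr(series, "mvpa_cadence_spm") <- mvpa_cadence_spm
  series
}

#' Collapse one day of epochs into a daily summary
#'
#' @param series an `epoch_series` whose epochs all start on one calendar
#'   day.
#' @param wear_complete externally supplied flag: did both the recording and
#'   its reference cover the full 24 h (non-wear detection is out of scope
#'   here and delegated to upstream QC)?
#' @param qc_pass externally supplied calibration QC flag.
#' @return A `daily_summary`: one-row data.frame with `date`, `total_steps`,
#'   `mvpa_steps`, `wear_complete`, `qc_pass`, `valid` (`wear_complete &
#'   qc_pass`).
#' @export
summarize_day <- function(series, wear_complete = TRUE, qc_pass = TRUE) {
  stopifnot(inherits(series, "epoch_series"))
  dates <- unique(as.Date(series$epoch_start, tz = "UTC"))
  if (length(dates) != 1L) {
    stop("epochs span more than one calendar day: ",
         paste(dates, collapse = ", "))
  }
  daily_summary(
    date = dates,
    total_steps = sum(series$steps),
    mvpa_steps = sum(series$steps[series$is_mvpa]),
    wear_complete = wear_complete, qc_pass = qc_pass
  )
}

#' @rdname summarize_day
#' @param date calendar date (`Date`).
#' @param total_steps,mvpa_steps non-negative daily totals,
#'   `mvpa_steps <= total_steps`.
#' @export
daily_summary <- function(date, total_steps, mvpa_steps,
                          wear_complete = TRUE, qc_pass = TRUE) {
  if (mvpa_steps > total_steps) stop("mvpa_steps must not exceed total_steps")
  if (total_steps < 0 || mvpa_steps < 0) stop("step totals must be >= 0")
  out <- data.frame(
    date = as.Date(date),
    total_steps = as.integer(round(total_steps)),
    mvpa_steps = as.integer(round(mvpa_steps)),
    wear_complete = isTRUE(wear_complete),
    qc_pass = isTRUE(qc_pass)
  )
  out$valid <- out$wear_complete & out$qc_pass
  class(out) <- c("daily_summary", "data.frame")
  out
}

#' Pair wrist and reference days
#'
#' Inner join on date of two sets of daily summaries, keeping only days valid
#' (complete wear and QC pass) on BOTH devices; output is in ascending date
#' order. Duplicate dates within one device are an error.
#'
#' @param wrist,reference data.frames of daily summaries (rows from
#'   [summarize_day()] / [daily_summary()], stackable with `rbind`).
#' @return A `paired_daily` data.frame with columns `date`, `wrist_total`,
#'   `reference_total`, `wrist_mvpa`, `reference_mvpa`.
#' @export
pair_days <- function(wrist, reference) {
  for (nm in list(list(wrist, "wrist"), list(reference, "reference"))) {
    if (anyDuplicated(nm[[1]]$date)) {
      stop("duplicate dates in ", nm[[2]], " summaries")
    }
  }
  w <- wrist[wrist$valid, c("date", "total_steps", "mvpa_steps")]
  r <- reference[reference$valid, c("date", "total_steps", "mvpa_steps")]
  names(w) <- c("date", "wrist_total", "wrist_mvpa")
  names(r) <- c("date", "reference_total", "reference_mvpa")
  out <- merge(w, r, by = "date", sort = TRUE)
  out <- out[, c("date", "wrist_total", "reference_total",
                 "wrist_mvpa", "reference_mvpa")]
  rownames(out) <- NULL
  class(out) <- c("paired_daily", "data.frame")
  out
}

#' Write an epoch series to CSV
#'
#' Columns `epoch_start,steps,cadence_spm,is_mvpa`; steps as integers,
#' cadence with 2 decimal places.
#' @param series an `epoch_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  dt <- data.table::data.table(
    epoch_start = format(series$epoch_start, "%Y-%m-%d %H:%M:%OS3"),
    steps = series$steps,
    cadence_spm = sprintf("%.2f", series$cadence_spm),
    is_mvpa = series$is_mvpa
  )
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Read / write daily summary CSVs
#'
#' Dialect: `date,total_steps,mvpa_steps,valid` (the `valid` flag folds
#' together complete wear and calibration QC, which are upstream inputs).
#' @param summaries a stacked daily-summary data.frame.
#' @param path file path.
#' @return the data read, or `path` invisibly for the writer.
#' @export
write_daily_csv <- function(summaries, path) {
  data.table::fwrite(
    summaries[, c("date", "total_steps", "mvpa_steps", "valid")],
    path, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_daily_csv
#' @export
read_daily_csv <- function(path) {
  dt <- data.table::fread(path, showProgress = FALSE)
  need <- c("date", "total_steps", "mvpa_steps", "valid")
  if (!all(need %in% names(dt))) {
    stop("daily CSV must have columns ", paste(need, collapse = ", "))
  }
  out <- data.frame(
    date = as.Date(dt$date),
    total_steps = as.integer(dt$total_steps),
    mvpa_steps = as.integer(dt$mvpa_steps),
    wear_complete = as.logical(dt$valid),
    qc_pass = as.logical(dt$valid)
  )
  out$valid <- as.logical(dt$valid)
  class(out) <- c("daily_summary", "data.frame")
  out
}
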