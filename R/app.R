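#' Pipeline run configuration
#'
#' @param params_preset preset name (`"verisense1"`/`"verisense2"`) or path
#'   to a parameter JSON (see [verisense_params()]).
#' @param epoch_length_s epoch length in seconds (default 5).
#' @param mvpa_cadence_spm MVPA cadence threshold (default 100 steps/min).
#' @param agreement_unit `"participant"` (default: one pair per input file,
#'   its mean over valid days) or `"day"` (one pair per valid day).
#' @param level confidence level for agreement statistics.
#' @param out_dir output directory (created if missing).
#' @return object of class `run_config`.
#' @export
run_config <- function(params_preset = "verisense2", epoch_length_s = 5,
                       mvpa_cadence_spm = 100,
                       agreement_unit = c("participant", "day"),
                       level = 0.95, out_dir = ".") {
  stopifnot(epoch_length_s > 0, mvpa_cadence_spm > 0)
  structure(
    list(params_preset = params_preset,
         params = verisense_params(params_preset),
         epoch_length_s = epoch_length_s,
         mvpa_cadence_spm = mvpa_cadence_spm,
         agreement_unit = match.arg(agreement_unit),
         level = level, out_dir = out_dir),
    class = "run_config"
  )
}

# Split a recording's step events into per-day epoch series anchored at
# midnight of each covered date.
events_to_daily <- function(events, recording, config,
                            wear_complete = TRUE, qc_pass = TRUE) {
  t0 <- as.numeric(recording$start_time)
  t1 <- t0 + duration_s(recording)
  d0 <- as.Date(recording$start_time, tz = "UTC")
  d1 <- as.Date(as.POSIXct(t1 - 1e-6, origin = "1970-01-01", tz = "UTC"),
                tz = "UTC")
  dates <- seq(d0, d1, by = "day")
  out <- lapply(dates, function(dd) {
    day_start <- as.numeric(as_naive_time(paste(dd, "00:00:00")))
    day_end <- day_start + 86400
    lo <- max(day_start, t0)
    hi <- min(day_end, t1)
    tt <- as.numeric(events$times)
    sel <- tt >= lo & tt < hi
    ev <- step_events(tt[sel], events$source_params)
    # epoch grid anchored at midnight, clipped to the recording span
    span_lo <- day_start +
      floor((lo - day_start) / config$epoch_length_s) * config$epoch_length_s
    ser <- aggregate_epochs(ev, config$epoch_length_s,
                            span = as.POSIXct(c(span_lo, hi),
                                              origin = "1970-01-01",
                                              tz = "UTC"))
    ser <- classify_mvpa(ser, config$mvpa_cadence_spm)
    covers_24h <- lo <= day_start + 1e-6 && hi >= day_end - 1e-6
    list(series = ser,
         summary = summarize_day(ser, wear_complete && covers_24h, qc_pass))
  })
  names(out) <- as.character(dates)
  out
}

#' Run the full pipeline on raw CSV inputs
#'
#' For every input raw CSV: count steps, aggregate to epochs, collapse to
#' daily summaries. If a reference daily CSV is given, pair valid days and
#' compute agreement statistics for total and MVPA steps. Writes per-input
#' epoch CSVs, a combined daily CSV, the paired-day CSV, `agreement.json`,
#' and `manifest.json` recording the preset name, every threshold, and the
#' package version. Reruns on identical inputs are byte-identical.
#'
#' @param config a [run_config()].
#' @param inputs character vector of raw CSV paths.
#' @param reference optional path to a reference daily CSV
#'   (`date,total_steps,mvpa_steps,valid`).
#' @return invisibly, a list with `daily`, `paired` (or NULL), `agreement`
#'   (or NULL) and the paths written.
#' @export
run_pipeline <- function(config, inputs, reference = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!length(inputs)) stop("no input files")
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) stop("input not found: ", paste(missing, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  all_daily <- list()
  paths <- character(0)
  for (path in inputs) {
    rec <- read_raw_csv(path)
    ev <- count_steps(rec, config$params)
    per_day <- events_to_daily(ev, rec, config)
    stem <- tools::file_path_sans_ext(basename(path))
    for (dd in names(per_day)) {
      ep_path <- file.path(config$out_dir,
                           sprintf("%s_%s_epochs.csv", stem, dd))
      write_epoch_csv(per_day[[dd]]$series, ep_path)
      paths <- c(paths, ep_path)
    }
    this_daily <- do.call(rbind, lapply(per_day, `[[`, "summary"))
    this_daily$participant <- stem
    all_daily[[path]] <- this_daily
  }
  daily <- do.call(rbind, all_daily)
  rownames(daily) <- NULL
  daily_path <- file.path(config$out_dir, "daily.csv")
  write_daily_csv(daily, daily_path)
  paths <- c(paths, daily_path)

  paired <- NULL
  agreement <- NULL
  if (!is.null(reference)) {
    if (!file.exists(reference)) {
      stop("reference daily file not found: ", reference)
    }
    ref <- read_daily_csv(reference)
    paired <- pair_days(daily, ref)
    paired$participant <- daily$participant[match(paired$date, daily$date)]
    paired_path <- file.path(config$out_dir, "paired.csv")
    data.table::fwrite(paired, paired_path, quote = FALSE)
    if (nrow(paired) >= 2L) {
      agreement <- list(
        total = unclass(agreement_analysis(paired, "total", config$level,
                                           config$agreement_unit)),
        mvpa = unclass(agreement_analysis(paired, "mvpa", config$level,
                                          config$agreement_unit))
      )
      agr_path <- file.path(config$out_dir, "agreement.json")
      jsonlite::write_json(agreement, agr_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      paths <- c(paths, paired_path, agr_path)
    } else {
      warning("fewer than 2 paired valid days; agreement skipped")
      paths <- c(paths, paired_path)
    }
  }

  manifest <- list(
    package = "stepsense",
    version = as.character(utils::packageVersion("stepsense")),
    params_preset = config$params_preset,
    thresholds = unclass(config$params),
    epoch_length_s = config$epoch_length_s,
    mvpa_cadence_spm = config$mvpa_cadence_spm,
    agreement_unit = config$agreement_unit,
    inputs = basename(inputs),
    reference = if (is.null(reference)) NULL else basename(reference)
  )
  man_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, man_path)
  invisible(list(daily = daily, paired = paired, agreement = agreement,
                 paths = paths))
}

# Minimal "--flag value" parser for the CLI (no external dependency).
parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands exposed by the `exec/stepsense` script:
#' \describe{
#'   \item{count}{`--input raw.csv --params verisense2 --epoch-seconds 5
#'     --out epochs.csv` — count steps and write the epoch CSV.}
#'   \item{daily}{`--input raw.csv --params verisense2 --out daily.csv` —
#'     daily summaries for one recording.}
#'   \item{agree}{`--pairs paired.csv --metric total --out agreement.json` —
#'     agreement statistics for an existing paired-day CSV.}
#'   \item{simulate}{`--seed 7 --out-dir sim/` — write the built-in example
#'     day (raw CSV, ground-truth JSON, reference daily CSV).}
#'   \item{pipeline}{`--input raw.csv --reference ref_daily.csv --params
#'     verisense2 --out-dir out/` — the full chain via [run_pipeline()].}
#' }
#'
#' @param args character vector of command-line arguments (subcommand
#'   first), e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
stepsense_cli <- function(args) {
  if (!length(args)) {
    cat("usage: stepsense <count|daily|agree|simulate|pipeline> [--flags]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- parse_cli_args(args[-1L])
  preset <- if (is.null(opt$params)) "verisense2" else opt$params
  status <- 0L
  switch(
    cmd,
    count = {
      rec <- read_raw_csv(opt$input)
      ev <- count_steps(rec, verisense_params(preset))
      epoch_s <- if (is.null(opt$`epoch-seconds`)) 5
        else as.numeric(opt$`epoch-seconds`)
      span <- recording_span(rec)
      ser <- aggregate_epochs(ev, epoch_s, span)
      write_epoch_csv(ser, opt$out)
      cat(sprintf("%d steps -> %s\n", length(ev), opt$out))
    },
    daily = {
      cfg <- run_config(preset, out_dir = dirname(opt$out))
      rec <- read_raw_csv(opt$input)
      ev <- count_steps(rec, cfg$params)
      per_day <- events_to_daily(ev, rec, cfg)
      daily <- do.call(rbind, lapply(per_day, `[[`, "summary"))
      write_daily_csv(daily, opt$out)
      cat(sprintf("%d day(s) -> %s\n", nrow(daily), opt$out))
    },
    agree = {
      pairs <- utils::read.csv(opt$pairs)
      metric <- if (is.null(opt$metric)) "total" else opt$metric
      res <- agreement_analysis(pairs, metric)
      jsonlite::write_json(unclass(res), opt$out, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      print(res)
    },
    simulate = {
      seed <- if (is.null(opt$seed)) 7L else as.integer(opt$seed)
      out_dir <- if (is.null(opt$`out-dir`)) "." else opt$`out-dir`
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      sim <- simulate_day(example_day_scenario(seed))
      write_raw_csv(sim$recording, file.path(out_dir, "wrist_raw.csv"))
      ref <- simulate_reference_device(sim$truth, seed = seed + 1L)
      write_daily_csv(ref, file.path(out_dir, "reference_daily.csv"))
      jsonlite::write_json(
        list(daily_total = sim$truth$daily_total,
             daily_mvpa = sim$truth$daily_mvpa,
             date = as.character(sim$truth$date), seed = seed),
        file.path(out_dir, "ground_truth.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      cat(sprintf("simulated day: %d steps (%d MVPA) -> %s\n",
                  sim$truth$daily_total, sim$truth$daily_mvpa, out_dir))
    },
    pipeline = {
      cfg <- run_config(preset,
                        out_dir = if (is.null(opt$`out-dir`)) "."
                          else opt$`out-dir`)
      run_pipeline(cfg, opt$input, reference = opt$reference)
      cat("pipeline complete ->", cfg$out_dir, "\n")
    },
    {
      cat("unknown subcommand:", cmd, "\n")
      status <- 2L
    }
  )
  invisible(status)
}

#' Span of a recording as a POSIXct pair
#'
#' @param recording a [raw_recording()].
#' @return POSIXct vector `c(start, end)` where end is
#'   `start + n / sample_rate_hz`.
#' @export
recording_span <- function(recording) {
  t0 <- as.numeric(recording$start_time)
  as.POSIXct(c(t0, t0 + duration_s(recording)), origin = "1970-01-01",
             tz = "UTC")
}
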