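read_input_csvs <- function(input_dir) {
  paths <- file.path(input_dir, c("comments.csv", "rumors.csv", "cases.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste("missing input file(s):", paste(missing, collapse = ", ")),
          class = "emolag_input_error")
  }
  list(
    comments = readr::read_csv(paths[1], show_col_types = FALSE),
    rumors = readr::read_csv(paths[2], show_col_types = FALSE),
    cases = readr::read_csv(paths[3], show_col_types = FALSE)
  )
}

run_summary <- function(run) {
  pairs <- summarise_pairs(run$ccf)
  list(
    manifest = run$manifest[c("config_hash", "seed", "mode", "n_days")],
    reliability = c(glance(run$kappa)[c("kappa", "n_items", "n_raters",
                                        "interpretation")],
                    list(unresolved_count = run$unresolved_count)),
    calibration = list(
      ratios = run$calibration$ratios$ratio,
      mean_ratio = run$calibration$mean_ratio,
      multiplier = run$calibration$multiplier,
      change_date = format(run$calibration$change_date)
    ),
    tallies = list(
      rumors = as.list(setNames(run$tallies$rumors$share,
                                run$tallies$rumors$category)),
      emotions = as.list(setNames(run$tallies$emotions$share,
                                  run$tallies$emotions$category))
    ),
    pairs = lapply(seq_len(nrow(pairs)), function(i) {
      as.list(pairs[i, c("pair", "peak_lag", "peak_r", "peak_p", "significant")])
    })
  )
}

summary_json <- function(run) {
  jsonlite::toJSON(run_summary(run), auto_unbox = TRUE, digits = NA,
                   na = "null", pretty = TRUE)
}

#' Run the full emotion-rumor-epidemic pipeline
#'
#' End-to-end orchestration: synthetic generation (or CSV ingestion), coder
#' consensus and interrater kappa, case-series calibration across the
#' diagnosis-criteria change, series assembly with category tallies, and the
#' full time-lagged cross-correlation comparison set. All randomness in
#' synthetic mode flows from the single seed in `config`, so two runs with
#' the same configuration produce byte-identical summaries.
#'
#' @param config A [synth_config()] (required in synthetic mode; in files
#'   mode only its calibration-date fields matter and it may be `NULL`).
#' @param mode `"synthetic"` (generate inputs) or `"files"` (read
#'   `comments.csv`, `rumors.csv`, `cases.csv` from `input_dir`).
#' @param input_dir Directory of input CSVs for files mode.
#' @param output_dir Optional directory; when given, every stage output and
#'   the summary JSON are written there.
#' @param max_lag,alpha Passed to the cross-correlation scan.
#' @param change_date,ratio_dates Calibration boundary and ratio days. In
#'   synthetic mode they default to the configuration's shock timing
#'   (change 2 days after the shock, ratios on the change day and the next);
#'   in files mode to the 2020-02-14 boundary and Feb 14-15 ratio days.
#' @return An object of class `emolag_run`: `manifest`, `kappa`,
#'   `unresolved_count`, `calibration`, `tallies`, `series`, `ccf`,
#'   `summary` (the serialized JSON string), plus the stage tables.
#' @export
#' @examples
#' run <- run_pipeline(synth_config(seed = 11, n_days = 40,
#'                                  comment_volume_mean = 60))
#' summarise_pairs(run$ccf)
run_pipeline <- function(config = NULL,
                         mode = c("synthetic", "files"),
                         input_dir = NULL, output_dir = NULL,
                         max_lag = 10, alpha = 0.05,
                         change_date = NULL, ratio_dates = NULL) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    if (!inherits(config, "synth_config")) {
      abort("synthetic mode requires a synth_config", class = "emolag_config_error")
    }
    study <- simulate_study(config)
    comments <- study$comments
    rumors <- study$rumors
    cases <- study$cases
    change_date <- as.Date(change_date %||%
                             (config$start_date + config$shock_day + 1L))
    seed <- config$seed
    n_days <- config$n_days
  } else {
    if (is.null(input_dir)) {
      abort("files mode requires input_dir", class = "emolag_input_error")
    }
    inputs <- read_input_csvs(input_dir)
    comments <- inputs$comments
    rumors <- inputs$rumors
    cases <- inputs$cases
    change_date <- as.Date(change_date %||% "2020-02-14")
    seed <- if (!is.null(config)) config$seed else NA_integer_
    n_days <- length(unique(as.Date(cases$date)))
    study <- NULL
  }
  ratio_dates <- as.Date(ratio_dates %||% (change_date + 0:1))

  comments <- add_consensus(comments)
  kappa <- interrater_kappa(comments)
  window <- range(as.Date(cases$date))
  emotion_daily <- consensus_counts_by_day(comments, window)
  unresolved_count <- sum(emotion_daily$unresolved)

  cal_hubei <- calibrate_series(cases, change_date = change_date,
                                ratio_dates = ratio_dates, region = "hubei")
  other <- dplyr::filter(cases, .data$region == "other")
  cal_other <- tibble(date = as.Date(other$date),
                      calibrated_count = other$reported_total)

  rumor_daily <- rumor_series(rumors, window)
  bundle <- build_series_bundle(emotion_daily, rumor_daily,
                                cal_hubei, cal_other, max_lag = max_lag)
  ccf <- run_all_pairs(bundle, max_lag = max_lag, alpha = alpha)

  tallies <- list(
    rumors = category_shares(
      setNames(colSums(rumor_daily[emotion_levels()]), emotion_levels()),
      digits = 1),
    emotions = category_shares(
      setNames(colSums(emotion_daily[emotion_levels()]), emotion_levels()),
      digits = 2)
  )

  manifest <- list(
    config_hash = rlang::hash(if (is.null(config)) list(mode = mode) else unclass(config)),
    seed = seed, mode = mode, n_days = n_days,
    max_lag = max_lag, alpha = alpha,
    input_dir = input_dir, package_version = as.character(utils::packageVersion("emolag"))
  )

  run <- structure(list(
    manifest = manifest, config = config, study = study,
    comments = comments, rumors = rumors, cases = cases,
    kappa = kappa, unresolved_count = unresolved_count,
    calibration = cal_hubei, calibration_other = cal_other,
    emotion_daily = emotion_daily, rumor_daily = rumor_daily,
    series = bundle, ccf = ccf, tallies = tallies
  ), class = "emolag_run")
  run$summary <- summary_json(run)

  if (!is.null(output_dir)) write_run_outputs(run, output_dir)
  run
}

#' Write every stage output of a pipeline run
#'
#' Emits `consensus.csv`, `reliability.json`, `calibrated_cases.csv`,
#' `calibration.json`, `series.csv`, `tallies.json`, one `ccf_<pair>.csv`
#' per comparison, and `summary.json`.
#'
#' @param run An `emolag_run`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_run_outputs <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(dplyr::select(run$comments, "comment_id", "date", "consensus"),
                   file.path(dir, "consensus.csv"))
  jsonlite::write_json(
    c(glance(run$kappa)[c("kappa", "n_items", "n_raters", "interpretation")],
      list(unresolved_count = run$unresolved_count)),
    file.path(dir, "reliability.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(run$calibration$calibrated,
                   file.path(dir, "calibrated_cases.csv"))
  jsonlite::write_json(
    list(ratios = run$calibration$ratios$ratio,
         mean_ratio = run$calibration$mean_ratio,
         multiplier = run$calibration$multiplier,
         change_date = format(run$calibration$change_date)),
    file.path(dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(run$series, file.path(dir, "series.csv"))
  jsonlite::write_json(
    list(rumors = run$tallies$rumors, emotions = run$tallies$emotions),
    file.path(dir, "tallies.json"), digits = NA)
  for (nm in names(run$ccf)) {
    readr::write_csv(tidy(run$ccf[[nm]]),
                     file.path(dir, paste0("ccf_", gsub("[^a-z_]", "_", nm), ".csv")))
  }
  writeLines(run$summary, file.path(dir, "summary.json"))
  invisible(dir)
}

#' Human-readable report of a pipeline run
#'
#' Tabulates category tallies (counts and shares), interrater reliability,
#' the calibration multiplier, and the peak lag/r/p of every comparison in
#' one document. Values are displayed rounded; the underlying run keeps full
#' precision. Regenerating the report from the same run is idempotent.
#'
#' @param run An `emolag_run`.
#' @return Character vector of report lines (invisibly printed with `cat`).
#' @export
make_report <- function(run) {
  stopifnot(inherits(run, "emolag_run"))
  pairs <- summarise_pairs(run$ccf)
  fmt_tally <- function(t, digits) {
    o <- order(-t$count)
    sprintf("    %-10s %8d  (%.*f%%)", t$category[o], t$count[o], digits, t$share[o])
  }
  lines <- c(
    "== Emotion-rumor infoveillance run ==",
    sprintf("mode: %s   seed: %s   days: %d", run$manifest$mode,
            run$manifest$seed, run$manifest$n_days),
    "",
    "-- Rumor categories --",
    fmt_tally(run$tallies$rumors, 1),
    "",
    "-- Emotion categories (consensus) --",
    fmt_tally(run$tallies$emotions, 2),
    sprintf("  unresolved comments: %d", run$unresolved_count),
    "",
    "-- Interrater reliability --",
    if (run$kappa$degenerate) {
      "  kappa undefined (single-category labels)"
    } else {
      sprintf("  Fleiss' kappa = %.2f (%s), %d items x %d raters",
              run$kappa$kappa, run$kappa$interpretation,
              run$kappa$n_items, run$kappa$n_raters)
    },
    "",
    "-- Case calibration --",
    sprintf("  post-change ratios %s -> mean %.2f, multiplier %.2f",
            paste(sprintf("%.2f", run$calibration$ratios$ratio), collapse = ", "),
            run$calibration$mean_ratio, run$calibration$multiplier),
    "",
    "-- Time-lagged cross-correlations (peak per pair) --"
  )
  any_sig <- FALSE
  for (i in seq_len(nrow(pairs))) {
    if (isTRUE(pairs$significant[i])) {
      any_sig <- TRUE
      lines <- c(lines, sprintf("  %-28s r = %+.2f at lag %+d (p = %.3g)",
                                pairs$pair[i], pairs$peak_r[i],
                                pairs$peak_lag[i], pairs$peak_p[i]))
    } else {
      lines <- c(lines, sprintf("  %-28s no significant peak at alpha = %g",
                                pairs$pair[i], run$manifest$alpha))
    }
  }
  if (!any_sig) {
    lines <- c(lines, "  (no pair shows a significant peak)")
  }
  lines
}

#' @export
print.emolag_run <- function(x, ...) {
  cat(make_report(x), sep = "\n")
  invisible(x)
}
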