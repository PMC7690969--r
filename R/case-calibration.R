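#' Clinical-to-nucleic diagnosis ratio
#'
#' Ratio of clinically diagnosed to nucleic-acid-confirmed cases for a day.
#' Display rounding (e.g. 8.44 for 13,332/1580) is a presentation concern;
#' the full-precision ratio is returned.
#'
#' @param clinical_count Non-negative count(s) of clinically diagnosed cases.
#' @param nucleic_count Positive count(s) of nucleic-acid-confirmed cases.
#' @return Numeric ratio(s).
#' @export
#' @examples
#' round(diagnosis_ratio(13332, 1580), 2)  # 8.44
diagnosis_ratio <- function(clinical_count, nucleic_count) {
  if (any(nucleic_count <= 0)) {
    abort("nucleic_count must be positive; the ratio is undefined at 0",
          class = "emolag_ratio_error")
  }
  if (any(clinical_count < 0)) {
    abort("clinical_count must be non-negative", class = "emolag_ratio_error")
  }
  clinical_count / nucleic_count
}

#' Calibration multiplier from post-change ratios
#'
#' One plus the arithmetic mean of the clinical-to-nucleic ratios observed
#' just after the diagnosis-criteria change. The mean is taken over the
#' unrounded ratios; rounding before averaging would be lossy.
#'
#' @param post_change_ratios Numeric vector of ratios (>= 0), length >= 1.
#' @return The multiplier `1 + mean(ratios)`.
#' @export
#' @examples
#' round(calibration_multiplier(c(1138 / 1282, 888 / 955)), 2)  # 1.91
calibration_multiplier <- function(post_change_ratios) {
  if (length(post_change_ratios) == 0) {
    abort("at least one post-change ratio is required", class = "emolag_ratio_error")
  }
  if (any(!is.finite(post_change_ratios)) || any(post_change_ratios < 0)) {
    abort("ratios must be finite and non-negative", class = "emolag_ratio_error")
  }
  1 + mean(post_change_ratios)
}

#' Calibrate a case series across a diagnosis-criteria change
#'
#' Implements the reporting-criteria correction: per-day clinical-to-nucleic
#' ratios are computed on `ratio_dates` (days just after the change), their
#' mean gives the multiplier `1 + mean_ratio`, and every day strictly before
#' `change_date` is rescaled to `nucleic_count * multiplier` while days on or
#' after `change_date` pass through as reported. This removes the one-time
#' backlog spike from the pre-change segment of the series.
#'
#' @param cases Tibble of daily records with `date`, `nucleic_count`,
#'   `clinical_count`, `reported_total` (optionally a `region` column,
#'   filtered via `region`). Dates must be contiguous.
#' @param change_date Date of the criteria change boundary (default the
#'   2020-02-14 analogue used by the reference analysis).
#' @param ratio_dates Dates whose clinical/nucleic ratios define the
#'   multiplier (default `change_date` and the following day); must fall on
#'   or after `change_date` and have positive nucleic counts.
#' @param region Optional region to filter `cases` to.
#' @param integer_output If `TRUE`, round calibrated values half-to-even to
#'   integers; the default keeps reals for downstream correlation.
#' @return An object of class `case_calibration`: `ratios` (per-day tibble),
#'   `mean_ratio`, `multiplier`, `change_date`, and `calibrated` (tibble of
#'   `date`, `calibrated_count`).
#' @export
#' @examples
#' cases <- simulate_epidemic(synth_config(seed = 1, count_noise = "none"))
#' cal <- calibrate_series(cases, region = "hubei",
#'                         change_date = as.Date("2020-01-20") + 25)
#' cal$multiplier  # 1.91 for the noise-free 0.91 clinical ratio
calibrate_series <- function(cases,
                             change_date = as.Date("2020-02-14"),
                             ratio_dates = change_date + 0:1,
                             region = NULL,
                             integer_output = FALSE) {
  cases <- as_tibble(cases)
  if (!is.null(region) && "region" %in% names(cases)) {
    cases <- dplyr::filter(cases, .data$region == !!region)
  }
  needed <- c("date", "nucleic_count", "clinical_count", "reported_total")
  missing_cols <- setdiff(needed, names(cases))
  if (length(missing_cols) > 0) {
    abort(paste("cases is missing columns:", paste(missing_cols, collapse = ", ")),
          class = "emolag_alignment_error")
  }
  cases <- dplyr::arrange(cases, .data$date)
  cases$date <- as.Date(cases$date)
  check_date_contiguous(cases$date, "case series")
  change_date <- as.Date(change_date)
  ratio_dates <- as.Date(ratio_dates)
  if (any(ratio_dates < change_date)) {
    abort("ratio_dates must fall on or after change_date",
          class = "emolag_ratio_error")
  }
  rd <- match(ratio_dates, cases$date)
  if (any(is.na(rd))) {
    abort("ratio_dates missing from the case series", class = "emolag_ratio_error")
  }
  ratios <- diagnosis_ratio(cases$clinical_count[rd], cases$nucleic_count[rd])
  mean_ratio <- mean(ratios)
  multiplier <- calibration_multiplier(ratios)
  calibrated <- ifelse(cases$date < change_date,
                       cases$nucleic_count * multiplier,
                       cases$reported_total)
  if (integer_output) calibrated <- round(calibrated)
  structure(list(
    ratios = tibble(date = ratio_dates, ratio = ratios),
    mean_ratio = mean_ratio,
    multiplier = multiplier,
    change_date = change_date,
    region = region,
    calibrated = tibble(date = cases$date, calibrated_count = calibrated),
    input = cases
  ), class = "case_calibration")
}

#' @export
print.case_calibration <- function(x, ...) {
  cat("Case-series calibration across a diagnosis-criteria change\n")
  cat(sprintf("  change date: %s\n", format(x$change_date)))
  cat(sprintf("  post-change ratios: %s (mean %.4f)\n",
              paste(sprintf("%.2f", x$ratios$ratio), collapse = ", "),
              x$mean_ratio))
  cat(sprintf("  multiplier: %.4f applied to %d pre-change day(s)\n",
              x$multiplier, sum(x$calibrated$date < x$change_date)))
  invisible(x)
}

#' @method tidy case_calibration
#' @export
tidy.case_calibration <- function(x, ...) {
  dplyr::left_join(
    dplyr::select(x$input, "date", "nucleic_count", "reported_total"),
    x$calibrated, by = "date"
  ) %>%
    dplyr::mutate(calibrated = .data$date < x$change_date)
}

#' @method glance case_calibration
#' @export
glance.case_calibration <- function(x, ...) {
  tibble(mean_ratio = x$mean_ratio, multiplier = x$multiplier,
         change_date = x$change_date, n_days = nrow(x$calibrated),
         n_ratio_days = nrow(x$ratios))
}

#' @method autoplot case_calibration
#' @export
autoplot.case_calibration <- function(object, ...) {
  df <- tidy(object) %>%
    tidyr::pivot_longer(c("reported_total", "calibrated_count"),
                        names_to = "series", values_to = "count") %>%
    dplyr::mutate(series = dplyr::recode(.data$series,
                                         reported_total = "reported",
                                         calibrated_count = "calibrated"))
  ggplot(df, aes(x = .data$date, y = .data$count, colour = .data$series)) +
    geom_line() +
    geom_point(size = 1) +
    geom_vline(xintercept = as.numeric(object$change_date), linetype = "dashed") +
    labs(x = NULL, y = "daily confirmed cases", colour = NULL,
         title = "Case series before and after calibration") +
    theme_minimal()
}
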