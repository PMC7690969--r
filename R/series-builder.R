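#' Daily rumor series, total and per emotion tag
#'
#' Counts rumors per day over a gap-free window, both in total and split by
#' emotion tag; per-tag series sum to the total elementwise and empty days
#' are explicit zeros. Rumors dated outside the window are excluded with a
#' warning giving the excluded count.
#'
#' @param rumors Tibble with `date` and `emotion_tag` columns.
#' @param window Date vector; its range defines the window. Defaults to the
#'   rumor date range.
#' @return Wide tibble: `date`, `total`, one column per emotion tag.
#' @export
#' @examples
#' r <- tibble::tibble(date = as.Date("2020-01-20") + c(0, 0, 0, 1),
#'                     emotion_tag = c("neutral", "fear", "fear", "anger"))
#' rumor_series(r)
rumor_series <- function(rumors, window = NULL) {
  check_labels(rumors$emotion_tag, "emotion_tag")
  window <- as.Date(window %||% range(rumors$date))
  days <- seq(min(window), max(window), by = "day")
  dates <- as.Date(rumors$date)
  outside <- sum(!(dates %in% days))
  if (outside > 0) {
    warn(sprintf("%d rumor(s) outside the window were excluded", outside))
    rumors <- rumors[dates %in% days, ]
    dates <- as.Date(rumors$date)
  }
  fd <- factor(as.character(dates), as.character(days))
  out <- tibble(date = days, total = as.integer(table(fd)))
  for (lab in emotion_levels()) {
    out[[lab]] <- as.integer(table(fd[rumors$emotion_tag == lab]))
  }
  out
}

#' Category counts and percentage shares
#'
#' Converts a category tally into counts plus percentage shares,
#' `100 * count / total`, rounded half-up at the displayed precision
#' (1 decimal place for rumor shares, 2 for emotion shares, by convention).
#'
#' @param counts Named integer vector of category counts, or a two-column
#'   data frame (`category`, `count`).
#' @param digits Decimal places for the share (default 1).
#' @param total Denominator; defaults to `sum(counts)` but may be supplied
#'   when shares are taken of a larger whole.
#' @return Tibble with `category`, `count`, `share`; the denominator is kept
#'   in the `total` attribute.
#' @export
#' @examples
#' category_shares(c(neutral = 176, fear = 62, happiness = 19,
#'                   anger = 12, sadness = 7))
category_shares <- function(counts, digits = 1, total = NULL) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts[[2]], counts[[1]])
  }
  if (any(counts < 0)) abort("counts must be non-negative", class = "emolag_tally_error")
  total <- total %||% sum(counts)
  if (total <= 0) abort("total must be positive", class = "emolag_tally_error")
  tibble(
    category = names(counts),
    count = as.integer(counts),
    share = unname(round_half_up(100 * counts / total, digits))
  ) %>%
    structure(total = total)
}

#' Log variance stabilization
#'
#' Elementwise natural `log(1 + x)`: daily count series contain zeros, for
#' which a plain log is undefined, and Pearson correlation downstream is
#' invariant to the log base.
#'
#' @param x Non-negative numeric vector.
#' @return `log1p(x)`.
#' @export
#' @examples
#' log_stabilize(c(0, exp(1) - 1))  # 0, 1
log_stabilize <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    abort("log stabilization requires non-negative values",
          class = "emolag_series_error")
  }
  log1p(x)
}

#' Align two daily tables to their common date range
#'
#' Trims both tables to the intersection of their date windows, the only
#' resolution of range mismatch that needs no imputation. Errors when the
#' overlap is shorter than `2 + 2 * max_lag` days, the minimum a lag scan up
#' to `max_lag` needs.
#'
#' @param a,b Tibbles with a `date` column and contiguous daily rows.
#' @param max_lag Largest lag the overlap must support (default 0).
#' @return List of the two trimmed tibbles.
#' @export
align_series <- function(a, b, max_lag = 0) {
  a$date <- as.Date(a$date); b$date <- as.Date(b$date)
  check_date_contiguous(a$date, "first series")
  check_date_contiguous(b$date, "second series")
  lo <- max(min(a$date), min(b$date))
  hi <- min(max(a$date), max(b$date))
  need <- 2 + 2 * max_lag
  if (lo > hi || as.integer(hi - lo) + 1 < need) {
    abort(sprintf("series overlap is shorter than the required minimum of %d days",
                  need),
          class = "emolag_alignment_error")
  }
  list(
    dplyr::filter(a, .data$date >= lo, .data$date <= hi),
    dplyr::filter(b, .data$date >= lo, .data$date <= hi)
  )
}

#' Assemble the log-stabilized series bundle for the lag scan
#'
#' Joins daily consensus-emotion counts, rumor counts and calibrated case
#' series on their common date range and log-stabilizes every series,
#' producing the wide table the full cross-correlation comparison set runs
#' on: calibrated cases for the focal and other region, the 4 emotion
#' series, total rumors, and the 4 same-emotion rumor series.
#'
#' @param emotion_daily Wide tibble from [consensus_counts_by_day()].
#' @param rumor_daily Wide tibble from [rumor_series()].
#' @param calibration_hubei `case_calibration` for the focal region.
#' @param calibration_other Optional `case_calibration` (or tibble of `date`,
#'   `calibrated_count`) for the other region.
#' @param max_lag Lag range the bundle must support (default 10).
#' @return Wide tibble: `date`, `cases_hubei`, `cases_other`, `happiness`,
#'   `sadness`, `anger`, `fear`, `rumors_total`, `rumors_happiness`,
#'   `rumors_sadness`, `rumors_anger`, `rumors_fear` — all `log1p` counts.
#' @export
build_series_bundle <- function(emotion_daily, rumor_daily,
                                calibration_hubei, calibration_other = NULL,
                                max_lag = 10) {
  cal_tbl <- function(x) {
    if (inherits(x, "case_calibration")) x$calibrated else as_tibble(x)
  }
  emo <- dplyr::select(emotion_daily, "date", dplyr::all_of(setdiff(emotion_levels(), "neutral")))
  rum <- rumor_daily %>%
    dplyr::select("date", rumors_total = "total",
                  rumors_happiness = "happiness", rumors_sadness = "sadness",
                  rumors_anger = "anger", rumors_fear = "fear")
  hub <- dplyr::rename(cal_tbl(calibration_hubei), cases_hubei = "calibrated_count")
  out <- hub
  if (!is.null(calibration_other)) {
    oth <- dplyr::rename(cal_tbl(calibration_other), cases_other = "calibrated_count")
    ab <- align_series(out, oth, max_lag = max_lag)
    out <- dplyr::inner_join(ab[[1]], ab[[2]], by = "date")
  }
  for (tbl in list(emo, rum)) {
    ab <- align_series(out, tbl, max_lag = max_lag)
    out <- dplyr::inner_join(ab[[1]], ab[[2]], by = "date")
  }
  dplyr::mutate(out, dplyr::across(-"date", log_stabilize))
}
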