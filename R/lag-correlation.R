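#' Pearson correlation at a single time lag
#'
#' Correlates `x` shifted forward by `k` days against `y` on the
#' `n - |k|` overlapping days:
#' `r(k) = cor(x[t + k], y[t])`. Under this convention a POSITIVE `k` means
#' `x` lags (follows) `y` by `k` days — e.g. a peak at `+1` for the pair
#' (happiness, rumors) reads "happiness lags the emergence of rumors by one
#' day", and a peak at `-1` for (rumors, cases) reads "rumors changed one
#' day in advance of the cases". The p-value comes from the two-sided t test
#' with `n_pairs - 2` degrees of freedom.
#'
#' A windowed segment with zero variance yields an explicit undefined-
#' correlation result (`r = NA`, `degenerate = TRUE`), never a silent 0.
#'
#' @param x,y Numeric vectors of equal length (aligned daily series).
#' @param k Integer lag, `|k| <= length(x) - 3`.
#' @return One-row tibble: `lag`, `r`, `p`, `n_pairs`, `degenerate`.
#' @export
#' @examples
#' lagged_pearson(1:10, 10:1, 0)$r  # -1
lagged_pearson <- function(x, y, k) {
  n <- length(x)
  if (length(y) != n) {
    abort("x and y must be aligned series of equal length",
          class = "emolag_alignment_error")
  }
  k <- as.integer(k)
  if (abs(k) > n - 3) {
    abort(sprintf("|lag| must be at most length - 3 = %d", n - 3),
          class = "emolag_lag_error")
  }
  if (k >= 0) {
    xs <- x[(1 + k):n]; ys <- y[1:(n - k)]
  } else {
    xs <- x[1:(n + k)]; ys <- y[(1 - k):n]
  }
  np <- n - abs(k)
  if (sd(xs) == 0 || sd(ys) == 0) {
    return(tibble(lag = k, r = NA_real_, p = NA_real_, n_pairs = np,
                  degenerate = TRUE))
  }
  r <- cor(xs, ys)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((np - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = np - 2)
  }
  tibble(lag = k, r = r, p = p, n_pairs = np, degenerate = FALSE)
}

#' Time-lagged cross-correlation scan
#'
#' Computes [lagged_pearson()] at every lag in `-max_lag..max_lag`, the 95%
#' envelope of an uncorrelated (white-noise) series,
#' `1.96 / sqrt(n - |k|)` per lag, and the peak: the lag maximizing `|r|`
#' among lags with `p < alpha`. Ties in `|r|` break toward the smallest
#' `|lag|`, then toward the negative lag. If no lag is significant the peak
#' fields are `NA` and `has_peak` is `FALSE`. No multiple-testing correction
#' is applied across the lags by default (a raw per-lag threshold, as in
#' standard lead-lag practice); `bonferroni = TRUE` multiplies p-values by
#' the number of lags.
#'
#' @param x,y Aligned numeric series (see [lagged_pearson()] for the lag-sign
#'   convention), length `> 2 * max_lag + 3`.
#' @param max_lag Largest lag scanned, in days (default 10).
#' @param alpha Per-lag significance threshold (default 0.05).
#' @param bonferroni Apply a Bonferroni correction across the scanned lags.
#' @param pair Optional `c(x_name, y_name)` used in printing and plots.
#' @return Object of class `emolag_ccf`: per-lag table plus `peak_lag`,
#'   `peak_r`, `peak_p`, `has_peak`, `n`, `max_lag`, `alpha`.
#' @export
#' @examples
#' set.seed(1)
#' w <- rnorm(120)
#' scan <- ccf_scan(c(w[3:120], rnorm(2)), w, max_lag = 5)
#' scan$peak_lag  # the shifted copy is recovered at +2
ccf_scan <- function(x, y, max_lag = 10, alpha = 0.05, bonferroni = FALSE,
                     pair = NULL) {
  n <- length(x)
  min_len <- 2 * max_lag + 4
  if (n < min_len) {
    abort(sprintf("series of length %d is too short for max_lag %d (minimum %d)",
                  n, max_lag, min_len),
          class = "emolag_lag_error")
  }
  lags <- seq(-max_lag, max_lag)
  tab <- map_dfr(lags, function(k) lagged_pearson(x, y, k))
  if (bonferroni) tab$p <- pmin(1, tab$p * length(lags))
  tab$envelope <- 1.96 / sqrt(tab$n_pairs)
  tab$significant <- !tab$degenerate & tab$p < alpha

  cand <- tab[tab$significant, , drop = FALSE]
  if (nrow(cand) > 0) {
    cand <- cand[order(-abs(cand$r), abs(cand$lag), cand$lag), , drop = FALSE]
    peak <- cand[1, ]
    res <- list(peak_lag = peak$lag, peak_r = peak$r, peak_p = peak$p,
                has_peak = TRUE)
  } else {
    res <- list(peak_lag = NA_integer_, peak_r = NA_real_, peak_p = NA_real_,
                has_peak = FALSE)
  }
  structure(c(list(table = tab, n = n, max_lag = as.integer(max_lag),
                   alpha = alpha, bonferroni = bonferroni,
                   pair = pair %||% c("x", "y")),
              res),
            class = "emolag_ccf")
}

#' @export
print.emolag_ccf <- function(x, ...) {
  cat(sprintf("Time-lagged cross-correlation: %s vs %s (n = %d, lags -%d..%d)\n",
              x$pair[1], x$pair[2], x$n, x$max_lag, x$max_lag))
  if (x$has_peak) {
    cat(sprintf("  peak r = %.3f at lag %+d (p = %.3g)\n",
                x$peak_r, x$peak_lag, x$peak_p))
    if (x$peak_lag > 0) {
      cat(sprintf("  reading: %s follows %s by %d day(s)\n",
                  x$pair[1], x$pair[2], x$peak_lag))
    } else if (x$peak_lag < 0) {
      cat(sprintf("  reading: %s leads %s by %d day(s)\n",
                  x$pair[1], x$pair[2], -x$peak_lag))
    } else {
      cat("  reading: the series move simultaneously\n")
    }
  } else {
    cat(sprintf("  no lag significant at alpha = %g\n", x$alpha))
  }
  invisible(x)
}

#' @method tidy emolag_ccf
#' @export
tidy.emolag_ccf <- function(x, ...) {
  x$table
}

#' @method glance emolag_ccf
#' @export
glance.emolag_ccf <- function(x, ...) {
  tibble(pair = paste(x$pair, collapse = "~"),
         peak_lag = x$peak_lag, peak_r = x$peak_r, peak_p = x$peak_p,
         significant = x$has_peak, n = x$n, max_lag = x$max_lag,
         alpha = x$alpha)
}

#' @method autoplot emolag_ccf
#' @export
autoplot.emolag_ccf <- function(object, ...) {
  tab <- tidy(object)
  p <- ggplot(tab, aes(x = .data$lag, y = .data$r)) +
    geom_hline(yintercept = 0, colour = "grey60") +
    geom_line(aes(y = .data$envelope), linetype = "dashed", colour = "grey40") +
    geom_line(aes(y = -.data$envelope), linetype = "dashed", colour = "grey40") +
    geom_segment(aes(xend = .data$lag, yend = 0)) +
    geom_point(aes(colour = .data$significant)) +
    scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
                        guide = "none") +
    labs(x = sprintf("lag of %s relative to %s (days)",
                     object$pair[1], object$pair[2]),
         y = "Pearson r",
         title = sprintf("Cross-correlation: %s vs %s",
                         object$pair[1], object$pair[2]),
         subtitle = "dashed: 95% envelope of an uncorrelated series") +
    theme_minimal()
  if (object$has_peak) {
    p <- p + annotate("point", x = object$peak_lag, y = object$peak_r,
                      shape = 1, size = 4, colour = "firebrick")
  }
  p
}

# The comparison set: each entry is c(x, y) with r(k) = cor(x[t+k], y[t]).
# Case pairs put rumors first so a negative peak lag reads "rumors changed
# in advance of the cases"; emotion pairs put the emotion first so a
# positive peak lag reads "the emotion follows the rumors".
standard_pairs <- function() {
  emotions <- setdiff(emotion_levels(), "neutral")
  c(
    list(c("rumors_total", "cases_hubei"),
         c("rumors_total", "cases_other")),
    lapply(emotions, function(e) c(e, "rumors_total")),
    lapply(emotions, function(e) c(e, paste0("rumors_", e)))
  )
}

#' Run the full cross-correlation comparison set
#'
#' Scans every pair of the standard comparison set on a log-stabilized series
#' bundle (see [build_series_bundle()]): total rumors against the calibrated
#' case series inside and outside the focal region, each of the 4 emotions
#' against total rumors, and each emotion against the same-emotion rumor
#' series.
#'
#' @param series Wide daily tibble containing `cases_hubei`, `cases_other`,
#'   the 4 emotion columns, `rumors_total` and the 4 `rumors_*` columns.
#' @param max_lag,alpha,bonferroni Passed to [ccf_scan()].
#' @return Named list of `emolag_ccf` objects, one per pair.
#' @export
run_all_pairs <- function(series, max_lag = 10, alpha = 0.05, bonferroni = FALSE) {
  pairs <- standard_pairs()
  needed <- unique(unlist(pairs))
  missing_cols <- setdiff(needed, names(series))
  if (length(missing_cols) > 0) {
    abort(paste("series bundle is missing:", paste(missing_cols, collapse = ", ")),
          class = "emolag_alignment_error")
  }
  res <- lapply(pairs, function(pr) {
    ccf_scan(series[[pr[1]]], series[[pr[2]]], max_lag = max_lag,
             alpha = alpha, bonferroni = bonferroni, pair = pr)
  })
  names(res) <- vapply(pairs, paste, character(1), collapse = "~")
  res
}

#' One-row-per-pair summary of a comparison set
#'
#' @param results Named list from [run_all_pairs()].
#' @return Tibble of [glance()] rows, one per pair.
#' @export
summarise_pairs <- function(results) {
  map_dfr(results, glance)
}
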