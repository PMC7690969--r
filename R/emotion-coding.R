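#' Consensus label for one comment's coder labels
#'
#' Returns the strictly most frequent label among the coders. When no strict
#' plurality winner exists (a tie), the comment is unresolved and
#' `NA_character_` is returned: inventing a priority order among emotions
#' would bias category shares, so ties are tracked instead of broken.
#'
#' @param labels Character vector of coder labels (length >= 3, values in
#'   [emotion_levels()]).
#' @return A single label, or `NA_character_` for unresolved ties.
#' @export
#' @examples
#' consensus_label(c("anger", "anger", "fear"))    # "anger"
#' consensus_label(c("anger", "fear", "neutral"))  # NA: three-way tie
consensus_label <- function(labels) {
  if (length(labels) < 3) {
    abort("coding protocol requires at least 3 coder labels per comment",
          class = "emolag_protocol_error")
  }
  check_labels(labels, "coder labels")
  tab <- table(factor(labels, emotion_levels()))
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) winners else NA_character_
}

coder_columns <- function(comments) {
  cols <- grep("^coder_", names(comments), value = TRUE)
  if (length(cols) < 3) {
    abort("comments must carry at least 3 coder_* columns",
          class = "emolag_protocol_error")
  }
  cols
}

# items x 5 matrix of per-category label counts; rows may be ragged via NA.
label_count_matrix <- function(labm) {
  lv <- emotion_levels()
  counts <- vapply(lv, function(l) rowSums(labm == l, na.rm = TRUE),
                   numeric(nrow(labm)))
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, lv))
  counts
}

#' Add a consensus column to a coded-comment table
#'
#' Vectorised strict-plurality consensus across all `coder_*` columns;
#' ties become `NA` (unresolved). Consensus is invariant to the order of the
#' coder columns.
#'
#' @param comments Tibble with `coder_1` ... `coder_k` columns (k >= 3).
#' @return The input tibble with a `consensus` column appended.
#' @export
#' @examples
#' tb <- tibble::tibble(comment_id = "c1", date = as.Date("2020-01-20"),
#'                      coder_1 = "fear", coder_2 = "fear", coder_3 = "anger")
#' add_consensus(tb)$consensus
add_consensus <- function(comments) {
  cols <- coder_columns(comments)
  labm <- as.matrix(comments[cols])
  check_labels(labm, "coder labels")
  counts <- label_count_matrix(labm)
  top <- apply(counts, 1, max)
  tied <- rowSums(counts == top) > 1
  consensus <- emotion_levels()[max.col(counts, ties.method = "first")]
  consensus[tied] <- NA_character_
  dplyr::mutate(as_tibble(comments), consensus = consensus)
}

kappa_interpretation <- function(kappa) {
  if (is.na(kappa)) return("undefined")
  if (kappa < 0) return("poor")
  if (kappa <= 0.20) return("slight")
  if (kappa <= 0.40) return("fair")
  if (kappa <= 0.60) return("moderate")
  if (kappa <= 0.80) return("substantial")
  "almost perfect"
}

#' Fleiss' kappa for multi-rater emotion coding
#'
#' Chance-corrected interrater agreement over the 5 emotion categories for a
#' fixed number of raters per item: observed agreement is the mean over items
#' of the pairwise rater agreement, expected agreement is the sum of squared
#' marginal category proportions, and
#' `kappa = (Po - Pe) / (1 - Pe)`. When items carry differing numbers of
#' labels (coders vary per comment), each item is deterministically
#' subsampled to the minimum common rater count (first k labels in stored
#' order) so the fixed-rater formula applies.
#'
#' If every label in the table falls in a single category, `Pe = 1` and kappa
#' is undefined; the result then carries `kappa = NA` with a `degenerate`
#' flag rather than propagating `NaN`.
#'
#' @param x Either a tibble with `coder_*` columns or an items-by-raters
#'   matrix/data frame of labels.
#' @return An object of class `fleiss_kappa` with fields `kappa`, `n_items`,
#'   `n_raters`, `Po`, `Pe`, `interpretation` (conventional bands:
#'   0.61-0.80 is "substantial"), `degenerate`.
#' @export
#' @examples
#' m <- rbind(c("anger", "anger"), c("anger", "fear"))
#' interrater_kappa(m)$kappa   # -1/3
interrater_kappa <- function(x) {
  labm <- if (is.data.frame(x) && any(grepl("^coder_", names(x)))) {
    as.matrix(x[coder_columns(x)])
  } else {
    as.matrix(x)
  }
  if (nrow(labm) < 2) {
    abort("kappa requires at least 2 items", class = "emolag_protocol_error")
  }
  check_labels(labm, "rater labels")
  n_avail <- rowSums(!is.na(labm))
  k <- min(n_avail)
  if (k < 2) {
    abort("kappa requires at least 2 raters per item", class = "emolag_protocol_error")
  }
  if (any(n_avail > k)) {
    # ragged coder counts: keep the first k stored labels of each item
    labm <- t(apply(labm, 1, function(r) r[!is.na(r)][seq_len(k)]))
  }
  counts <- label_count_matrix(labm[, seq_len(k), drop = FALSE])
  n <- nrow(counts)
  po_i <- (rowSums(counts^2) - k) / (k * (k - 1))
  po <- mean(po_i)
  p_j <- colSums(counts) / (n * k)
  pe <- sum(p_j^2)
  degenerate <- (1 - pe) < 1e-12
  kappa <- if (degenerate) NA_real_ else (po - pe) / (1 - pe)
  structure(list(kappa = kappa, n_items = n, n_raters = as.integer(k),
                 Po = po, Pe = pe,
                 interpretation = kappa_interpretation(kappa),
                 degenerate = degenerate),
            class = "fleiss_kappa")
}

#' @export
print.fleiss_kappa <- function(x, ...) {
  cat("Fleiss' kappa over 5 emotion categories\n")
  cat(sprintf("  items: %d   raters: %d\n", x$n_items, x$n_raters))
  if (x$degenerate) {
    cat("  kappa: undefined (no marginal variance; all labels identical)\n")
  } else {
    cat(sprintf("  Po = %.4f   Pe = %.4f   kappa = %.4f (%s)\n",
                x$Po, x$Pe, x$kappa, x$interpretation))
  }
  invisible(x)
}

#' @method glance fleiss_kappa
#' @export
glance.fleiss_kappa <- function(x, ...) {
  tibble(kappa = x$kappa, n_items = x$n_items, n_raters = x$n_raters,
         Po = x$Po, Pe = x$Pe, interpretation = x$interpretation,
         degenerate = x$degenerate)
}

#' Daily consensus counts per emotion category
#'
#' Tallies, for each day of a gap-free window, the number of comments whose
#' consensus equals each of the 5 labels. Unresolved comments (tied coders)
#' are counted in none of the 5 series but reported in a residual
#' `unresolved` column, so per day
#' `happiness + ... + neutral + unresolved = total comments`.
#'
#' @param comments Tibble with `date` and `consensus` columns (see
#'   [add_consensus()]).
#' @param window Date vector; its range defines the (gap-free) window.
#'   Defaults to the comment date range. Comments outside the window are
#'   dropped with a warning.
#' @return Wide tibble: `date`, one count column per label, `unresolved`.
#' @export
consensus_counts_by_day <- function(comments, window = NULL) {
  if (!"consensus" %in% names(comments)) comments <- add_consensus(comments)
  window <- as.Date(window %||% range(comments$date))
  if (length(window) < 1 || all(is.na(window))) {
    abort("window is empty", class = "emolag_alignment_error")
  }
  days <- seq(min(window), max(window), by = "day")
  outside <- sum(!(as.Date(comments$date) %in% days))
  if (outside > 0) {
    warn(sprintf("%d comment(s) outside the window were dropped", outside))
    comments <- dplyr::filter(comments, as.Date(.data$date) %in% days)
  }
  fd <- factor(as.character(as.Date(comments$date)), as.character(days))
  out <- tibble(date = days)
  for (lab in emotion_levels()) {
    out[[lab]] <- as.integer(table(fd[!is.na(comments$consensus) &
                                        comments$consensus == lab]))
  }
  out$unresolved <- as.integer(table(fd[is.na(comments$consensus)]))
  out
}
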