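#' The five emotion categories
#'
#' The closed label set used throughout the package: the four basic human
#' emotions plus "neutral" for comments carrying no emotional information.
#'
#' @return Character vector of length 5, in canonical order.
#' @export
#' @examples
#' emotion_levels()
emotion_levels <- function() {
  c("happiness", "sadness", "anger", "fear", "neutral")
}

# Emotions treated as negative when coupling to epidemic severity.
negative_emotions <- function() c("anger", "fear")

#' Round half away from zero
#'
#' Commercial ("half-up") rounding at a fixed number of decimal places, used
#' for displayed percentage shares. Base R's `round()` rounds half to even,
#' which does not reproduce conventionally printed shares.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.5, 0)   # 3, where round(2.5) gives 2
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # 1e-9 guards against binary representation of values sitting at .5
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Deterministic per-stage seed substream: adding a stage never perturbs the
# draws of earlier stages, and all stage seeds stay below 2^31 - 1.
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  m <- 2147483647
  as.integer(((as.numeric(seed) %% m) * 7919 + h * 104729) %% m)
}

with_stage_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stage))
  force(code)
}

check_date_contiguous <- function(dates, what = "series") {
  dates <- as.Date(dates)
  if (length(dates) < 2) {
    abort(sprintf("%s must span at least 2 days", what), class = "emolag_alignment_error")
  }
  if (any(diff(sort(unique(dates))) != 1)) {
    abort(sprintf("%s has date gaps; daily series must be gap-free", what),
          class = "emolag_alignment_error")
  }
  invisible(dates)
}

check_labels <- function(x, arg = "labels") {
  bad <- setdiff(unique(as.character(x[!is.na(x)])), emotion_levels())
  if (length(bad) > 0) {
    abort(sprintf("%s contains values outside the 5 emotion categories: %s",
                  arg, paste(bad, collapse = ", ")),
          class = "emolag_label_error")
  }
  invisible(x)
}
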