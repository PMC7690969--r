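#' Configuration for the coupled epidemic-emotion-rumor generator
#'
#' Bundles every knob of the synthetic-data generator into a validated list.
#' The defaults describe the study conditions the pipeline is exercised
#' under: a roughly 50-day window, an epidemic wave with a one-time
#' diagnosis-criteria shock part-way through, a neutral-dominant emotion
#' mixture with anger > fear > happiness ~ sadness, and a rumor stream
#' lag-coupled to the negative-emotion count.
#'
#' @param seed Integer seed; every random draw in a run flows from it via
#'   documented per-stage substreams.
#' @param n_days Number of consecutive days simulated (default 50).
#' @param start_date First calendar day of the window.
#' @param epidemic_growth_rate Per-day multiplicative growth of the epidemic
#'   mean curve before its peak (> 1 grows; the curve decays at the same rate
#'   after the peak).
#' @param epidemic_peak_day 1-based day index of the epidemic peak (default
#'   day 20, pulled inward for windows shorter than 50 days).
#' @param epidemic_peak_cases Expected nucleic-acid-confirmed cases at the peak
#'   in the focal region.
#' @param shock_day 1-based day index of the diagnosis-criteria change, when
#'   the withheld clinical-diagnosis backlog starts being reported. Must lie
#'   strictly inside the window (default day 24, pulled inward for short
#'   windows so the post-change ratio days still exist).
#' @param shock_clinical_ratio True clinical-to-nucleic ratio (default 0.91).
#' @param shock_dump_split Fractions of the backlog released on `shock_day`
#'   and `shock_day + 1`; must be two non-negative numbers summing to 1.
#' @param other_region_scale Size of the non-focal region's epidemic relative
#'   to the focal one; the non-focal region has no clinical-diagnosis channel
#'   and therefore no reporting shock.
#' @param count_noise Noise family for daily counts: `"poisson"` (default),
#'   `"nbinom"` (negative binomial, for overdispersed volumes), or `"none"`
#'   (deterministic expected values, useful for exact-arithmetic checks).
#' @param nb_size Negative-binomial size parameter when `count_noise = "nbinom"`.
#' @param comment_volume_mean Expected comments per day.
#' @param emotion_base_probs Named length-5 probability vector over
#'   [emotion_levels()], summing to 1; the latent emotion mixture when the
#'   epidemic signal is zero.
#' @param emotion_case_coupling Gain linking `log(1 + cases)` to the odds of
#'   the negative emotions (anger, fear); 0 decouples emotions from the
#'   epidemic.
#' @param rumor_volume_mean Expected rumors per day.
#' @param rumor_lag_days Signed lag injected between rumors and the
#'   negative-emotion count: the rumor intensity on day `t` tracks the
#'   emotion signal on day `t + rumor_lag_days`, so a cross-correlation scan
#'   of (emotion, rumors) peaks at `rumor_lag_days` under this package's lag
#'   convention. Must satisfy `|rumor_lag_days| <= 10`.
#' @param rumor_coupling_strength Target correlation (in \[0, 1\]) between the
#'   latent rumor intensity and the shifted emotion signal; the measured
#'   count-level correlation is attenuated slightly by sampling noise.
#' @param rumor_log_sd Log-scale standard deviation of the daily rumor
#'   intensity around its mean.
#' @param rumor_tag_probs Named length-5 probability vector for the emotion
#'   tag attached to each rumor; neutral is modal by default.
#' @param n_coders Number of simulated coders per comment (>= 3).
#' @param coder_accuracy Probability a coder reports a comment's true latent
#'   label; otherwise one of the other four labels is reported uniformly.
#'
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(seed = 1)
#' cfg$n_days
synth_config <- function(seed,
                         n_days = 50L,
                         start_date = as.Date("2020-01-20"),
                         epidemic_growth_rate = 1.2,
                         epidemic_peak_day = NULL,
                         epidemic_peak_cases = 2000,
                         shock_day = NULL,
                         shock_clinical_ratio = 0.91,
                         shock_dump_split = c(0.8, 0.2),
                         other_region_scale = 0.25,
                         count_noise = c("poisson", "nbinom", "none"),
                         nb_size = 10,
                         comment_volume_mean = 2000,
                         emotion_base_probs = c(happiness = 0.0125, sadness = 0.0113,
                                                anger = 0.1297, fear = 0.0362,
                                                neutral = 0.8103),
                         emotion_case_coupling = 0.05,
                         rumor_volume_mean = 5.5,
                         rumor_lag_days = 0L,
                         rumor_coupling_strength = 0.48,
                         rumor_log_sd = 0.6,
                         rumor_tag_probs = c(happiness = 0.069, sadness = 0.025,
                                             anger = 0.043, fear = 0.225,
                                             neutral = 0.638),
                         n_coders = 3L,
                         coder_accuracy = 0.95) {
  count_noise <- match.arg(count_noise)
  bad_cfg <- function(msg) abort(msg, class = "emolag_config_error")

  if (missing(seed) || length(seed) != 1 || is.na(seed)) bad_cfg("seed is mandatory")
  seed <- as.integer(seed)
  n_days <- as.integer(n_days)
  if (n_days < 3) bad_cfg("n_days must be at least 3")
  # defaults scale into short windows; at the canonical 50-day window they
  # sit at day 24 (shock) and day 20 (epidemic peak)
  shock_day <- shock_day %||% max(1L, min(24L, n_days - 4L))
  epidemic_peak_day <- epidemic_peak_day %||%
    min(20L, max(2L, as.integer(round(n_days * 0.4))))
  if (epidemic_growth_rate <= 0) bad_cfg("epidemic_growth_rate must be positive")
  if (epidemic_peak_cases <= 0) bad_cfg("epidemic_peak_cases must be positive")
  if (comment_volume_mean <= 0) bad_cfg("comment_volume_mean must be positive")
  if (rumor_volume_mean <= 0) bad_cfg("rumor_volume_mean must be positive")
  if (shock_day <= 0 || shock_day >= n_days) {
    bad_cfg("shock_day must lie strictly inside (0, n_days)")
  }
  if (length(shock_dump_split) != 2 || any(shock_dump_split < 0) ||
      abs(sum(shock_dump_split) - 1) > 1e-9) {
    bad_cfg("shock_dump_split must be two non-negative fractions summing to 1")
  }
  for (nm in c("emotion_base_probs", "rumor_tag_probs")) {
    p <- get(nm)
    if (length(p) != 5 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      bad_cfg(sprintf("%s must be 5 non-negative entries summing to 1", nm))
    }
    if (is.null(names(p))) names(p) <- emotion_levels()
    if (!setequal(names(p), emotion_levels())) {
      bad_cfg(sprintf("%s must be named by the 5 emotion categories", nm))
    }
    assign(nm, p[emotion_levels()])
  }
  if (coder_accuracy <= 0 || coder_accuracy > 1) {
    bad_cfg("coder_accuracy must lie in (0, 1]")
  }
  n_coders <- as.integer(n_coders)
  if (n_coders < 3) bad_cfg("n_coders must be at least 3")
  rumor_lag_days <- as.integer(rumor_lag_days)
  if (abs(rumor_lag_days) > 10) bad_cfg("|rumor_lag_days| must be at most 10")
  if (abs(rumor_lag_days) >= n_days) bad_cfg("|rumor_lag_days| must be below n_days")
  if (rumor_coupling_strength < 0 || rumor_coupling_strength > 1) {
    bad_cfg("rumor_coupling_strength must lie in [0, 1]")
  }

  structure(list(
    seed = seed, n_days = n_days, start_date = as.Date(start_date),
    epidemic_growth_rate = epidemic_growth_rate,
    epidemic_peak_day = as.integer(epidemic_peak_day),
    epidemic_peak_cases = epidemic_peak_cases,
    shock_day = as.integer(shock_day),
    shock_clinical_ratio = shock_clinical_ratio,
    shock_dump_split = as.numeric(shock_dump_split),
    other_region_scale = other_region_scale,
    count_noise = count_noise, nb_size = nb_size,
    comment_volume_mean = comment_volume_mean,
    emotion_base_probs = emotion_base_probs,
    emotion_case_coupling = emotion_case_coupling,
    rumor_volume_mean = rumor_volume_mean,
    rumor_lag_days = rumor_lag_days,
    rumor_coupling_strength = rumor_coupling_strength,
    rumor_log_sd = rumor_log_sd,
    rumor_tag_probs = rumor_tag_probs,
    n_coders = n_coders, coder_accuracy = coder_accuracy
  ), class = "synth_config")
}

# Draw daily counts around a mean curve under the configured noise family.
draw_counts <- function(mu, config) {
  switch(config$count_noise,
         poisson = rpois(length(mu), mu),
         nbinom  = rnbinom(length(mu), mu = mu, size = config$nb_size),
         none    = mu)
}

#' Simulate epidemic case counts with a diagnosis-criteria shock
#'
#' Generates daily nucleic-acid-confirmed and clinically diagnosed counts for
#' a focal region plus a smaller non-focal region. The focal region's mean
#' curve grows exponentially to `epidemic_peak_day` and decays symmetrically.
#' Clinical diagnoses run at `shock_clinical_ratio` times the nucleic count
#' every day, but before `shock_day` they are withheld from `reported_total`;
#' the accumulated backlog is released on `shock_day` and `shock_day + 1`
#' (split per `shock_dump_split`), producing the characteristic one-time
#' reporting spike. From `shock_day` onward `reported_total` includes both
#' channels daily, so the total reported over the window equals the total of
#' true cases (backlog conservation).
#'
#' @param config A [synth_config()].
#' @return A tibble with one row per day per region: `date`, `region`
#'   (`"hubei"`-like focal vs `"other"`), `nucleic_count`, `clinical_count`,
#'   `reported_total`, and the latent ledger column `true_total`
#'   (= nucleic + clinical, the series calibration should recover).
#' @export
#' @examples
#' cases <- simulate_epidemic(synth_config(seed = 1))
#' head(cases)
simulate_epidemic <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_days
  day <- seq_len(n)
  dates <- config$start_date + day - 1L
  mu <- config$epidemic_peak_cases *
    config$epidemic_growth_rate^(-abs(day - config$epidemic_peak_day))

  focal <- with_stage_seed(config$seed, "epidemic", {
    nucleic <- draw_counts(mu, config)
    clinical <- if (config$count_noise == "none") {
      config$shock_clinical_ratio * nucleic
    } else {
      rpois(n, config$shock_clinical_ratio * nucleic)
    }
    list(nucleic = nucleic, clinical = clinical)
  })
  nucleic <- focal$nucleic
  clinical <- focal$clinical

  s <- config$shock_day
  backlog <- sum(clinical[day < s])
  if (config$count_noise == "none") {
    dump1 <- config$shock_dump_split[1] * backlog
  } else {
    dump1 <- round(config$shock_dump_split[1] * backlog)
  }
  dump2 <- backlog - dump1

  reported <- ifelse(day < s, nucleic, nucleic + clinical)
  reported[day == s] <- reported[day == s] + dump1
  if (s + 1 <= n) reported[day == s + 1] <- reported[day == s + 1] + dump2

  other <- with_stage_seed(config$seed, "epidemic_other", {
    draw_counts(mu * config$other_region_scale, config)
  })

  dplyr::bind_rows(
    tibble(date = dates, region = "hubei",
           nucleic_count = nucleic, clinical_count = clinical,
           reported_total = reported, true_total = nucleic + clinical),
    tibble(date = dates, region = "other",
           nucleic_count = other, clinical_count = 0 * other,
           reported_total = other, true_total = other)
  )
}

# Per-day latent label probabilities: negative-emotion odds tilted upward by
# the epidemic signal, linear in log(1 + cases).
emotion_day_probs <- function(config, case_signal) {
  base <- config$emotion_base_probs
  tilt <- exp(config$emotion_case_coupling * log1p(case_signal))
  w <- matrix(rep(base, each = length(case_signal)),
              nrow = length(case_signal),
              dimnames = list(NULL, names(base)))
  w[, negative_emotions()] <- w[, negative_emotions()] * tilt
  w / rowSums(w)
}

#' Simulate a coder-labelled comment stream
#'
#' Draws a daily comment volume around `comment_volume_mean`, assigns each
#' comment a latent true emotion from the base mixture tilted toward anger
#' and fear by the epidemic signal, and has each of `n_coders` simulated
#' coders report the true label with probability `coder_accuracy` (otherwise
#' a uniformly random other label). Consensus is deliberately left to the
#' coding stage.
#'
#' @param config A [synth_config()].
#' @param cases Case table from [simulate_epidemic()] (the national true-case
#'   signal, summed over regions, drives the emotion tilt). Must cover the
#'   configured window.
#' @return A tibble with `comment_id`, `date`, the latent ledger column
#'   `true_label`, and coder columns `coder_1` ... `coder_k`.
#' @export
simulate_comments <- function(config, cases) {
  stopifnot(inherits(config, "synth_config"))
  dates <- config$start_date + seq_len(config$n_days) - 1L
  sig <- cases %>%
    dplyr::group_by(date) %>%
    dplyr::summarise(cases = sum(.data$true_total), .groups = "drop")
  if (!all(dates %in% sig$date)) {
    abort("cases table does not cover the configured window",
          class = "emolag_alignment_error")
  }
  sig <- sig$cases[match(dates, sig$date)]
  probs <- emotion_day_probs(config, sig)
  lv <- emotion_levels()

  with_stage_seed(config$seed, "comments", {
    vol <- draw_counts(rep(config$comment_volume_mean, config$n_days), config)
    vol <- as.integer(round(vol))
    # per-day multinomial split over latent labels, expanded to comments
    day_lab <- lapply(seq_len(config$n_days), function(i) {
      stats::rmultinom(1, vol[i], probs[i, ])[, 1]
    })
    true_idx <- unlist(lapply(day_lab, function(ct) rep.int(seq_along(lv), ct)),
                       use.names = FALSE)
    n_total <- length(true_idx)
    out <- tibble(
      comment_id = sprintf("c%07d", seq_len(n_total)),
      date = rep(dates, times = vapply(day_lab, sum, integer(1))),
      true_label = lv[true_idx]
    )
    for (j in seq_len(config$n_coders)) {
      correct <- runif(n_total) < config$coder_accuracy
      # a wrong coder picks uniformly among the 4 other labels
      offset <- sample.int(4L, n_total, replace = TRUE)
      wrong_idx <- ((true_idx - 1L + offset) %% 5L) + 1L
      out[[paste0("coder_", j)]] <- ifelse(correct, lv[true_idx], lv[wrong_idx])
    }
    out
  })
}

# Daily latent true-label counts from the comment stream's ledger column.
latent_daily_counts <- function(config, comments) {
  dates <- config$start_date + seq_len(config$n_days) - 1L
  out <- tibble(date = dates)
  for (lab in emotion_levels()) {
    d <- comments$date[comments$true_label == lab]
    out[[lab]] <- as.integer(table(factor(as.character(d), as.character(dates))))
  }
  out
}

#' Simulate a rumor stream lag-coupled to negative emotions
#'
#' The daily rumor intensity is a log-normal mixture of an independent noise
#' component and the standardized (log-scale) negative-emotion count shifted
#' by `rumor_lag_days`, mixed so their latent correlation equals
#' `rumor_coupling_strength`; daily rumor counts are then drawn from the
#' configured count family and each rumor receives an emotion tag from
#' `rumor_tag_probs` (neutral modal). Days whose shifted emotion index falls
#' outside the window receive pure noise.
#'
#' @param config A [synth_config()].
#' @param emotions Wide daily tibble of per-label emotion counts (`date` plus
#'   the 5 label columns), e.g. the generator's latent ledger or consensus
#'   counts. Must cover the configured window.
#' @return A tibble with `rumor_id`, `date`, `emotion_tag`.
#' @export
simulate_rumors <- function(config, emotions) {
  stopifnot(inherits(config, "synth_config"))
  dates <- config$start_date + seq_len(config$n_days) - 1L
  if (!all(dates %in% as.Date(emotions$date))) {
    abort("emotion series do not cover the configured window",
          class = "emolag_alignment_error")
  }
  if (abs(config$rumor_lag_days) >= config$n_days) {
    abort("|rumor_lag_days| must be below n_days", class = "emolag_config_error")
  }
  neg <- rowSums(as.matrix(emotions[match(dates, as.Date(emotions$date)),
                                    negative_emotions()]))
  e <- log1p(neg)
  e <- if (sd(e) > 0) (e - mean(e)) / sd(e) else rep(0, length(e))

  n <- config$n_days
  L <- config$rumor_lag_days
  rho <- config$rumor_coupling_strength
  with_stage_seed(config$seed, "rumors", {
    eta <- rnorm(n)
    spare <- rnorm(n)
    src_idx <- seq_len(n) + L
    src <- ifelse(src_idx >= 1 & src_idx <= n, e[pmin(pmax(src_idx, 1L), n)], NA_real_)
    src[is.na(src)] <- spare[is.na(src)]
    z <- rho * src + sqrt(1 - rho^2) * eta
    lambda <- config$rumor_volume_mean * exp(config$rumor_log_sd * z -
                                               config$rumor_log_sd^2 / 2)
    counts <- if (config$count_noise == "none") round(lambda) else
      draw_counts(lambda, config)
    counts <- as.integer(counts)
    tags <- sample(emotion_levels(), sum(counts), replace = TRUE,
                   prob = config$rumor_tag_probs)
    tibble(
      rumor_id = sprintf("r%05d", seq_len(sum(counts))),
      date = rep(dates, times = counts),
      emotion_tag = tags
    )
  })
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining [simulate_epidemic()], [simulate_comments()]
#' and [simulate_rumors()] under one seed, returning all tables plus the
#' latent daily emotion ledger used by recovery tests.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_study` with elements `config`, `cases`,
#'   `comments`, `latent_daily`, `rumors`.
#' @export
#' @examples
#' study <- simulate_study(synth_config(seed = 7, n_days = 30,
#'                                      comment_volume_mean = 50))
#' names(study)
simulate_study <- function(config) {
  cases <- simulate_epidemic(config)
  comments <- simulate_comments(config, cases)
  latent <- latent_daily_counts(config, comments)
  rumors <- simulate_rumors(config, latent)
  structure(list(config = config, cases = cases, comments = comments,
                 latent_daily = latent, rumors = rumors),
            class = "synth_study")
}

#' Write a synthetic study to the pipeline's CSV input format
#'
#' Emits `comments.csv` (comment_id, date, coder_1..k), `rumors.csv`
#' (rumor_id, date, emotion_tag) and `cases.csv` (date, region,
#' nucleic_count, clinical_count, reported_total), UTF-8 with ISO-8601 dates.
#' Latent ledger columns are not written.
#'
#' @param study A `synth_study` from [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_csv <- function(study, dir) {
  stopifnot(inherits(study, "synth_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    comments = file.path(dir, "comments.csv"),
    rumors = file.path(dir, "rumors.csv"),
    cases = file.path(dir, "cases.csv")
  )
  readr::write_csv(dplyr::select(study$comments, -"true_label"), paths["comments"])
  readr::write_csv(study$rumors, paths["rumors"])
  readr::write_csv(dplyr::select(study$cases, -"true_total"), paths["cases"])
  invisible(paths)
}
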