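test_that("config validation rejects impossible study conditions", {
  expect_s3_class(synth_config(seed = 1), "synth_config")
  expect_error(synth_config(seed = 1, epidemic_growth_rate = -1),
               class = "emolag_config_error")
  expect_error(synth_config(seed = 1, comment_volume_mean = 0),
               class = "emolag_config_error")
  expect_error(synth_config(seed = 1, shock_day = 50, n_days = 50),
               class = "emolag_config_error")
  expect_error(synth_config(seed = 1, emotion_base_probs = rep(0.25, 4)),
               class = "emolag_config_error")
  expect_error(synth_config(seed = 1, coder_accuracy = 0),
               class = "emolag_config_error")
  expect_error(synth_config(seed = 1, n_coders = 2),
               class = "emolag_config_error")
  expect_error(synth_config(seed = 1, rumor_lag_days = 11),
               class = "emolag_config_error")
})

test_that("noise-free epidemic keeps the clinical ratio exact on every day", {
  cases <- simulate_epidemic(synth_config(seed = 3, count_noise = "none",
                                          shock_clinical_ratio = 0.91))
  hub <- dplyr::filter(cases, region == "hubei")
  expect_equal(hub$clinical_count / hub$nucleic_count,
               rep(0.91, nrow(hub)))
})

test_that("backlog dumped at the criteria change conserves total cases", {
  for (noise in c("poisson", "none")) {
    cfg <- synth_config(seed = 1, n_days = 50, shock_day = 23,
                        count_noise = noise)
    hub <- dplyr::filter(simulate_epidemic(cfg), region == "hubei")
    expect_equal(sum(hub$reported_total),
                 sum(hub$nucleic_count + hub$clinical_count))
    expect_equal(hub$true_total, hub$nucleic_count + hub$clinical_count)
    # pre-shock days report the nucleic channel only
    pre <- hub[seq_len(cfg$shock_day - 1), ]
    expect_equal(pre$reported_total, pre$nucleic_count)
    # the dump days carry the withheld backlog in the configured split
    backlog <- sum(pre$clinical_count)
    s <- cfg$shock_day
    extra <- hub$reported_total[s + 0:1] -
      (hub$nucleic_count[s + 0:1] + hub$clinical_count[s + 0:1])
    expect_equal(sum(extra), backlog)
    expect_equal(extra[1] / max(backlog, 1), 0.8, tolerance = 0.05)
  }
})

test_that("seeded generator runs are bit-identical", {
  cfg <- synth_config(seed = 99, n_days = 20, comment_volume_mean = 30)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cases, s2$cases)
  expect_identical(s1$comments, s2$comments)
  expect_identical(s1$rumors, s2$rumors)
})

test_that("perfect coders always agree with the latent label", {
  study <- small_study(seed = 5, coder_accuracy = 1)
  cc <- study$comments
  expect_identical(cc$coder_1, cc$true_label)
  expect_identical(cc$coder_2, cc$true_label)
  expect_identical(cc$coder_3, cc$true_label)
})

test_that("uncoupled uniform emotion mixture yields ~equal label shares", {
  cfg <- synth_config(seed = 8, n_days = 30, comment_volume_mean = 2000,
                      emotion_case_coupling = 0,
                      emotion_base_probs = setNames(rep(0.2, 5), emotion_levels()))
  study <- simulate_study(cfg)
  n <- nrow(study$comments)
  se <- sqrt(0.2 * 0.8 / n)
  shares <- table(study$comments$true_label) / n
  expect_true(all(abs(shares - 0.2) < 3 * se))
})

test_that("per-coder agreement with truth matches the configured accuracy", {
  acc <- 0.8
  cfg <- synth_config(seed = 13, n_days = 10, comment_volume_mean = 1500,
                      coder_accuracy = acc)
  study <- simulate_study(cfg)
  cc <- study$comments
  n <- nrow(cc)
  expect_gte(n, 10000)
  se <- sqrt(acc * (1 - acc) / n)
  for (j in 1:3) {
    agree <- mean(cc[[paste0("coder_", j)]] == cc$true_label)
    expect_lt(abs(agree - acc), 3 * se)
  }
})

test_that("uncoupled rumors stay inside the envelope at any fixed lag", {
  # per-lag false-alarm rate at the nominal 5% level, well under 10%
  res <- null_false_alarm_experiment(seed = 4, n_reps = 60, n_days = 100,
                                     comment_volume_mean = 60)
  expect_lte(res$false_alarm_rate, 0.10)
})

test_that("strong lag-0 coupling is recovered as a lag-0 peak", {
  scan <- emolag:::emotion_rumor_scan(seed = 21, n_days = 200,
                                      comment_volume_mean = 150,
                                      strength = 0.9, lag = 0, max_lag = 10)
  expect_true(scan$has_peak)
  expect_identical(scan$peak_lag, 0L)
})

test_that("rumor stream carries neutral as the modal tag", {
  study <- small_study(seed = 31, n_days = 50, volume = 30)
  tags <- table(factor(study$rumors$emotion_tag, emotion_levels()))
  expect_identical(names(which.max(tags)), "neutral")
})

test_that("synthetic CSV round-trips through the documented schema", {
  dir <- withr::local_tempdir()
  study <- small_study(seed = 77, n_days = 12, volume = 10)
  write_synthetic_csv(study, dir)
  cc <- readr::read_csv(file.path(dir, "comments.csv"), show_col_types = FALSE)
  expect_named(cc, c("comment_id", "date", "coder_1", "coder_2", "coder_3"))
  ca <- readr::read_csv(file.path(dir, "cases.csv"), show_col_types = FALSE)
  expect_named(ca, c("date", "region", "nucleic_count", "clinical_count",
                     "reported_total"))
  expect_setequal(unique(ca$region), c("hubei", "other"))
})
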