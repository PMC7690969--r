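test_that("strict-plurality consensus resolves majorities and flags ties", {
  expect_identical(consensus_label(c("anger", "anger", "fear")), "anger")
  expect_identical(consensus_label(c("fear", "fear", "fear")), "fear")
  expect_identical(consensus_label(c("anger", "fear", "neutral")),
                   NA_character_)
  expect_identical(consensus_label(c("anger", "anger", "fear", "fear")),
                   NA_character_)
  expect_error(consensus_label(c("anger", "fear")),
               class = "emolag_protocol_error")
  expect_error(consensus_label(c("anger", "anger", "joy")),
               class = "emolag_label_error")
})

test_that("consensus is invariant to coder order", {
  set.seed(11)
  lv <- emotion_levels()
  for (i in 1:50) {
    labs <- sample(lv, sample(3:6, 1), replace = TRUE)
    expect_identical(consensus_label(labs), consensus_label(rev(labs)))
    expect_identical(consensus_label(labs), consensus_label(sample(labs)))
  }
})

test_that("vectorised consensus matches the single-comment rule", {
  set.seed(7)
  lv <- emotion_levels()
  tb <- tibble::tibble(
    comment_id = sprintf("c%03d", 1:200),
    date = as.Date("2020-01-20") + (0:199 %% 10),
    coder_1 = sample(lv, 200, TRUE),
    coder_2 = sample(lv, 200, TRUE),
    coder_3 = sample(lv, 200, TRUE)
  )
  got <- add_consensus(tb)$consensus
  want <- vapply(seq_len(200), function(i) {
    r <- consensus_label(c(tb$coder_1[i], tb$coder_2[i], tb$coder_3[i]))
    if (is.na(r)) NA_character_ else r
  }, character(1))
  expect_identical(got, want)
})

test_that("Fleiss' kappa reproduces hand-computed and boundary cases", {
  # unanimity across >=2 categories
  m <- cbind(rep(c("anger", "fear"), 5), rep(c("anger", "fear"), 5),
             rep(c("anger", "fear"), 5))
  expect_equal(interrater_kappa(m)$kappa, 1)
  # frozen hand computation: Po = 0.5, Pe = 0.75^2 + 0.25^2 = 0.625
  m2 <- rbind(c("anger", "anger"), c("anger", "fear"))
  k2 <- interrater_kappa(m2)
  expect_equal(k2$Po, 0.5)
  expect_equal(k2$Pe, 0.625)
  expect_equal(k2$kappa, -1 / 3)
  expect_identical(k2$interpretation, "poor")
  # single-category table: expected agreement 1, kappa undefined
  m3 <- matrix("neutral", 4, 3)
  k3 <- interrater_kappa(m3)
  expect_true(k3$degenerate)
  expect_true(is.na(k3$kappa))
  expect_identical(k3$interpretation, "undefined")
})

test_that("kappa stays in [-1, 1] and hits 1 only under unanimity", {
  set.seed(3)
  lv <- emotion_levels()
  for (i in 1:40) {
    m <- matrix(sample(lv, 30, TRUE), nrow = 10)
    k <- interrater_kappa(m)
    if (!k$degenerate) {
      expect_gte(k$kappa, -1)
      expect_lte(k$kappa, 1)
      unanimous <- all(apply(m, 1, function(r) length(unique(r)) == 1))
      expect_identical(isTRUE(all.equal(k$kappa, 1)), unanimous)
    }
  }
})

test_that("perfect synthetic coders give kappa 1", {
  study <- small_study(seed = 2, coder_accuracy = 1)
  expect_equal(interrater_kappa(study$comments)$kappa, 1)
})

test_that("ragged coder counts are subsampled to the common rater count", {
  tb <- tibble::tibble(
    coder_1 = c("anger", "anger", "fear"),
    coder_2 = c("anger", "fear", "fear"),
    coder_3 = c("anger", "anger", "fear"),
    coder_4 = c("anger", NA, NA)
  )
  k <- interrater_kappa(tb)
  expect_identical(k$n_raters, 3L)
  expect_equal(k$kappa, interrater_kappa(tb[, 1:3])$kappa)
})

test_that("daily consensus counts conserve the comment total", {
  study <- small_study(seed = 15, volume = 60, coder_accuracy = 0.6)
  cc <- add_consensus(study$comments)
  daily <- consensus_counts_by_day(cc, range(study$latent_daily$date))
  per_day_total <- rowSums(daily[c(emotion_levels(), "unresolved")])
  expect_equal(per_day_total,
               as.numeric(table(factor(as.character(cc$date),
                                       as.character(daily$date)))))
  expect_equal(sum(per_day_total), nrow(cc))
  expect_gt(sum(daily$unresolved), 0)
})

test_that("perfect coders make consensus counts equal the latent ledger", {
  study <- small_study(seed = 23, coder_accuracy = 1)
  daily <- consensus_counts_by_day(add_consensus(study$comments),
                                   range(study$latent_daily$date))
  for (lab in emotion_levels()) {
    expect_equal(daily[[lab]], study$latent_daily[[lab]])
  }
  expect_true(all(daily$unresolved == 0))
})

test_that("three comments on one day tally into the right label series", {
  tb <- tibble::tibble(
    comment_id = c("a", "b", "c"),
    date = as.Date("2020-02-01"),
    coder_1 = c("anger", "anger", "fear"),
    coder_2 = c("anger", "anger", "fear"),
    coder_3 = c("fear", "neutral", "fear")
  )
  daily <- consensus_counts_by_day(add_consensus(tb),
                                   as.Date(c("2020-02-01", "2020-02-02")))
  expect_equal(daily$anger, c(2L, 0L))
  expect_equal(daily$fear, c(1L, 0L))
  expect_equal(daily$happiness, c(0L, 0L))
})
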