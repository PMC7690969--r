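test_that("lagged Pearson handles the elementary anchor cases", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(lagged_pearson(x, x, 0)$r, 1)
  expect_equal(lagged_pearson(x, rev(x), 0)$r, -1)
  # hand-rolled value on the 5 overlapping pairs at lag 1
  got <- lagged_pearson(c(2, 1, 4, 3, 6, 5), c(1, 2, 3, 4, 5, 6), 1)
  want <- oracle_lagged_pearson(c(2, 1, 4, 3, 6, 5), c(1, 2, 3, 4, 5, 6), 1)
  expect_equal(got$r, want$r)
  expect_equal(got$n_pairs, 5L)
  expect_error(lagged_pearson(x, x[-1], 0), class = "emolag_alignment_error")
  expect_error(lagged_pearson(x, x, 4), class = "emolag_lag_error")
})

test_that("r and p match the brute-force oracle to 1e-12", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(20:60, 1)
    k <- sample(-10:10, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    got <- lagged_pearson(x, y, k)
    want <- oracle_lagged_pearson(x, y, k)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_identical(got$n_pairs, as.integer(want$n))
  }
})

test_that("zero-variance segments yield an explicit undefined result", {
  x <- rep(3, 40)
  y <- rnorm(40)
  lp <- lagged_pearson(x, y, 2)
  expect_true(lp$degenerate)
  expect_true(is.na(lp$r))
  scan <- ccf_scan(x, y, max_lag = 5)
  expect_true(all(tidy(scan)$degenerate))
  expect_false(scan$has_peak)
})

test_that("an exact two-day shift is recovered at lag +2", {
  set.seed(33)
  y <- rnorm(200)
  x <- c(y[3:200], rnorm(2))  # x[t] = y[t + 2]  =>  x[t - 2] = y[t]
  scan <- ccf_scan(x, y, max_lag = 10)
  expect_identical(scan$peak_lag, -2L)
  expect_gt(scan$peak_r, 0.95)
  # mirrored construction peaks at +2
  scan2 <- ccf_scan(y, x, max_lag = 10)
  expect_identical(scan2$peak_lag, 2L)
  for (k in -10:10) {
    want <- oracle_lagged_pearson(x, y, k)
    expect_equal(tidy(scan)$r[k + 11], want$r, tolerance = 1e-12)
  }
})

test_that("ccf is symmetric under swapping the series and negating the lag", {
  set.seed(55)
  x <- rnorm(60)
  y <- rnorm(60)
  a <- tidy(ccf_scan(x, y, max_lag = 8))
  b <- tidy(ccf_scan(y, x, max_lag = 8))
  expect_equal(a$r, rev(b$r))
  expect_equal(a$n_pairs, rev(b$n_pairs))
})

test_that("r is invariant under positive affine transforms (log-base free)", {
  set.seed(66)
  x <- rexp(80)
  y <- rexp(80)
  a <- tidy(ccf_scan(x, y, max_lag = 6))
  b <- tidy(ccf_scan(2.5 * x + 7, 0.3 * y + 1, max_lag = 6))
  expect_equal(a$r, b$r, tolerance = 1e-12)
  # natural-log vs log10 stabilization gives identical correlations
  c1 <- tidy(ccf_scan(log1p(x), y, max_lag = 6))
  c2 <- tidy(ccf_scan(log1p(x) / log(10), y, max_lag = 6))
  expect_equal(c1$r, c2$r, tolerance = 1e-12)
})

test_that("the envelope narrows with overlap and the scan rejects short series", {
  set.seed(9)
  scan <- ccf_scan(rnorm(50), rnorm(50), max_lag = 10)
  tab <- tidy(scan)
  expect_equal(tab$envelope, 1.96 / sqrt(50 - abs(tab$lag)))
  expect_equal(tab$n_pairs, 50 - abs(tab$lag))
  expect_error(ccf_scan(rnorm(20), rnorm(20), max_lag = 10), "minimum",
               class = "emolag_lag_error")
})

test_that("peak ties break toward the smallest then negative lag", {
  tab <- tibble::tibble(lag = c(-2L, -1L, 1L, 3L),
                        r = c(0.8, 0.8, 0.8, 0.9))
  ord <- order(-abs(tab$r), abs(tab$lag), tab$lag)
  expect_identical(tab$lag[ord[1]], 3L)       # highest |r| wins outright
  tab2 <- tab[tab$r == 0.8, ]
  ord2 <- order(-abs(tab2$r), abs(tab2$lag), tab2$lag)
  expect_identical(tab2$lag[ord2[1]], -1L)    # then smallest |lag|, negative first
  # end to end: palindromic series make r(k) = r(-k) exactly; the +/-1 tie
  # resolves to the negative lag
  set.seed(77)
  half <- rnorm(20)
  y <- c(half, rev(half))
  x <- c(y[2:40], y[1]) + c(y[40], y[1:39])  # circular y[t-1] + y[t+1]
  scan <- ccf_scan(x, y, max_lag = 5)
  tab <- tidy(scan)
  expect_identical(tab$r[tab$lag == 1], tab$r[tab$lag == -1])
  expect_identical(scan$peak_lag, -1L)
})

test_that("white-noise peaks exceed the envelope at the family-wise rate", {
  set.seed(202)
  n <- 120
  hits <- vapply(1:300, function(i) {
    tab <- tidy(ccf_scan(rnorm(n), rnorm(n), max_lag = 10))
    any(abs(tab$r) > tab$envelope)
  }, logical(1))
  # 21 lags at ~5% each: family-wise ~ 1 - 0.95^21 = 0.66
  expect_lt(abs(mean(hits) - (1 - 0.95^21)), 0.12)
})

test_that("the standard comparison set runs and reports every pair", {
  study <- small_study(seed = 18, n_days = 30, volume = 40)
  daily <- consensus_counts_by_day(add_consensus(study$comments),
                                   range(study$latent_daily$date))
  rum <- rumor_series(study$rumors, range(study$latent_daily$date))
  cal <- calibrate_series(study$cases, region = "hubei",
                          change_date = study$config$start_date +
                            study$config$shock_day + 1)
  other <- dplyr::filter(study$cases, region == "other")
  bundle <- build_series_bundle(daily, rum, cal,
                                tibble::tibble(date = other$date,
                                               calibrated_count = other$reported_total))
  res <- run_all_pairs(bundle)
  expect_length(res, 10)
  expect_named(res, c("rumors_total~cases_hubei", "rumors_total~cases_other",
                      "happiness~rumors_total", "sadness~rumors_total",
                      "anger~rumors_total", "fear~rumors_total",
                      "happiness~rumors_happiness", "sadness~rumors_sadness",
                      "anger~rumors_anger", "fear~rumors_fear"))
  summ <- summarise_pairs(res)
  expect_equal(nrow(summ), 10)
  expect_error(run_all_pairs(dplyr::select(bundle, -"anger")), "anger",
               class = "emolag_alignment_error")
})

test_that("an injected emotion-rumor lag surfaces in the full comparison set", {
  scan <- emolag:::emotion_rumor_scan(seed = 71, n_days = 200,
                                      comment_volume_mean = 150,
                                      strength = 0.8, lag = 1, max_lag = 10)
  expect_identical(scan$peak_lag, 1L)  # emotions follow rumors by one day
})
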