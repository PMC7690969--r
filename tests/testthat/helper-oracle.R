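# Brute-force lagged-Pearson oracle, written independently of the package's
# correlation path: explicit loop alignment, raw-sum Pearson formula, and a
# p-value via the incomplete-beta form of the two-sided t test.
oracle_lagged_pearson <- function(x, y, k) {
  xs <- numeric(0)
  ys <- numeric(0)
  for (t in seq_along(y)) {
    if (t + k >= 1 && t + k <= length(x)) {
      xs <- c(xs, x[t + k])
      ys <- c(ys, y[t])
    }
  }
  m <- length(xs)
  dx <- xs - sum(xs) / m
  dy <- ys - sum(ys) / m
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  df <- m - 2
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  list(r = r, p = p, n = m)
}

# Tiny synthetic study used across tests: small volumes keep it fast.
small_study <- function(seed = 42, n_days = 30, volume = 40, ...) {
  simulate_study(synth_config(seed = seed, n_days = n_days,
                              comment_volume_mean = volume, ...))
}
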