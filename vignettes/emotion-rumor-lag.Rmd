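---
title: "Methods: consensus emotion coding, case calibration, and lagged cross-correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus emotion coding, case calibration, and lagged cross-correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emolag)
```

emolag analyses the interplay of three daily count streams observed during
an epidemic: manually coded public emotions in social-media comments,
emotion-tagged online rumors, and confirmed case counts. This vignette is
the package's account of the statistical choices behind each stage, the
parameters that matter, and what the synthetic-data experiments do and do
not demonstrate.

## The coding model

Comments are classified into five categories — the four basic human emotions
(happiness, sadness, anger, fear) plus neutral — by at least three coders
each. The final label is the **strict plurality** vote. The protocol only
specifies that conflicts are resolved by majority; it leaves genuinely tied
votes (e.g. three coders, three different labels) undefined. We deliberately
do not break ties: any priority order over emotions would bias the category
shares, which are themselves an analysis endpoint. Tied comments carry an
explicit unresolved marker, are excluded from all five per-label series, and
are reported as a residual count, so conservation holds exactly:
per day, the five label counts plus the unresolved count equal the comment
total.

Interrater reliability is **Fleiss' kappa**. With at least three raters
whose identity may vary across items, Cohen's two-rater form does not apply;
Fleiss' form assumes only a fixed number of labels per item. Observed
agreement `Po` is the mean over items of the pairwise rater agreement,
expected agreement `Pe` is the sum of squared marginal category proportions,
and `kappa = (Po - Pe)/(1 - Pe)`. When coder counts vary per comment, each
item is subsampled to the minimum common rater count, deterministically
(first k labels in stored order), so the statistic is reproducible. A table
whose labels all fall in one category has `Pe = 1`; kappa is then undefined
and the result says so explicitly (`degenerate = TRUE`, kappa `NA`) instead
of propagating `NaN`. Interpretation uses the conventional bands
(0.61–0.80 = "substantial").

## Case-count calibration

When diagnosis criteria change mid-series — clinically diagnosed cases
suddenly counted alongside nucleic-acid confirmations — the accumulated
backlog of clinical diagnoses is released over about two days, producing a
spike that makes the raw reported series incomparable across the change.
The correction assumes the clinical-to-nucleic ratio observed just *after*
the change (when the backlog has cleared) reflects the steady-state ratio
that also held before it:

* per-day ratios `clinical / nucleic` are computed on the ratio days
  (defaults: the change day and the following day);
* their arithmetic mean `m` gives the multiplier `1 + m`;
* every day strictly before the change date is rescaled to
  `nucleic * (1 + m)`; days on or after the change pass through as reported.

Two numerical choices matter. The mean is taken over **unrounded** ratios —
rounding to two decimals before averaging is lossy and nothing implies it.
Calibrated values are kept as reals; correlation downstream does not want
re-rounding (an integer output option rounds half-to-even). Days on/after
the change date — including the dump days themselves — pass through
unchanged; the boundary and ratio days are parameters, so the procedure
generalizes to any timeline, synthetic ones included.

The calibration is linear (calibrating `c·x` gives `c·` the calibrated
series), is the identity when the mean ratio is 0, and on a noise-free
synthetic epidemic with true clinical ratio 0.91 recovers the multiplier
1.91 and the latent true series exactly (to double rounding).

## Series assembly

Daily series are gap-free by construction: empty days are explicit zeros,
never missing. Sources with different windows are trimmed to their
intersection — the only resolution needing no imputation. Before
correlation every series is variance-stabilized with the natural
`log(1 + x)`: daily rumor counts contain zeros, so a plain log is
undefined, and Pearson correlation is invariant to the log base (an affine
rescaling), so the base is immaterial. No smoothing, detrending,
differencing, or seasonal adjustment is applied anywhere.

Percentage shares are rounded **half up** at display precision (1 decimal
for rumor shares, 2 for emotion shares) because that is how such tallies
are conventionally printed; base R's half-to-even `round()` is not. One
quirk follows from the arithmetic: a tally of 12 anger rumors out of 276
computes to 4.3% at one decimal, whatever the rounding rule.

## The lag scan

For aligned series `x`, `y` and integer lag `k`, the scan computes
`r(k) = cor(x[t + k], y[t])` over the `n - |k|` overlapping days.
**Sign convention:** a positive `k` means `x` lags (follows) `y` by `k`
days. The convention is fixed so that the two verbal readings of interest
come out naturally: in the pair (happiness, rumors) a peak at `+1` reads
"happiness lags the emergence of rumors by one day", and in the pair
(rumors, cases) a peak at `-1` reads "rumors changed one day in advance of
the cases". The standard comparison set orders its pairs accordingly:
rumors first against each region's cases, the emotion first against rumors.

Per lag, the p-value is the two-sided t test with `n - |k| - 2` degrees of
freedom, and the dashed **95% envelope** is `1.96 / sqrt(n - |k|)` — the
large-sample white-noise approximation, the standard choice for
cross-correlogram reference bands. The **peak** is the lag maximizing `|r|`
among lags significant at `alpha = 0.05`; using `|r|` surfaces negative
peaks with their sign. Ties in `|r|` break toward the smallest `|lag|`
(the most parsimonious lead/lag), then toward the negative lag — an
arbitrary but documented order. If no lag is significant the result carries
an explicit no-peak marker. A zero-variance window yields an explicit
undefined-correlation flag, never a silent zero.

Two caveats are intentional properties, not bugs. First, no
multiple-testing correction is applied across the 21 lags: the scan uses a
raw per-lag threshold (a Bonferroni option exists, off by default).
Consequently the family-wise chance of *some* lag exceeding the envelope
under independence is about `1 - 0.95^21 ≈ 0.66`, and the test suite
verifies exactly that. Second, the p-value reported at the peak is the
per-lag p; selecting the maximum across lags inflates it, so the peak p
should be read as descriptive, not as a family-wise error rate.

## The synthetic-data generator

The generator emulates the structure the analysis assumes, under one seed
fanned out to per-stage substreams (so adding a stage never perturbs
earlier draws; two runs of one configuration are bit-identical).

* **Epidemic**: the mean nucleic-acid curve grows at
  `epidemic_growth_rate` (default 1.2/day) to a peak (2000 cases at day 20
  of the canonical 50-day window) and decays symmetrically; daily counts
  are Poisson around it (negative-binomial and noise-free options exist —
  Poisson is the simplest family for non-negative integer daily counts).
  Clinical diagnoses run at `shock_clinical_ratio` (default 0.91) times the
  nucleic count but are withheld from the reported total before the shock
  day (default day 24); the backlog is released 0.8/0.2 over the shock day
  and the next, mirroring a two-day clearance, and conservation is exact:
  total reported equals total true cases. A second, smaller region (scale
  0.25) has no clinical channel and hence no shock.
* **Comments**: daily volume is Poisson around `comment_volume_mean`
  (default 2000/day); each comment's latent label is drawn from
  `emotion_base_probs` — defaults echo the ordering neutral ≫ anger > fear >
  happiness ≈ sadness — with the anger/fear odds tilted by
  `emotion_case_coupling × log(1 + cases)`, a linear-in-log-counts tilt
  that keeps probabilities valid for any gain. Each of `n_coders` (3)
  reports the true label with probability `coder_accuracy` (0.95),
  otherwise a uniformly random other label. Under these defaults the
  realized Fleiss' kappa lands in the substantial band (≈ 0.78) — the skewed
  neutral-heavy marginals depress kappa well below the raw accuracy.
* **Rumors**: the daily latent intensity is log-normal around
  `rumor_volume_mean` (default 5.5/day) with its Gaussian kernel mixed as
  `z = ρ·e[t + L] + sqrt(1 − ρ²)·η`, where `e` is the standardized
  log-scale negative-emotion count, `L = rumor_lag_days`, and
  `ρ = rumor_coupling_strength` (default 0.48, a contemporaneous-coupling
  magnitude of the order reported for anger-rumor pairs in infoveillance
  work). Counts are Poisson around the intensity, and each rumor draws a
  tag from `rumor_tag_probs` (neutral modal). Because `ρ` is the
  correlation of the *latent* intensity, the measured count-level
  correlation is attenuated by Poisson noise on both sides — at the default
  volumes a target of 0.48 measures around 0.35 on 200-day windows. The
  injected lag, not the attenuated magnitude, is the recoverable quantity.

What the generator does **not** emulate: real comment text (comments carry
labels only), coder biases that are correlated across coders or categories,
weekly seasonality and news-cycle bursts in posting volume, rumor cascades
(each day's count is conditionally independent given the intensity), and
reporting artifacts beyond the single criteria change. Passing tests on
synthetic data therefore demonstrate the pipeline's arithmetic and its
ability to recover known structure — not that real emotion-rumor coupling
has any particular strength.

## The recovery experiments

`lag_recovery_experiment()` injects coupling 0.6 at each lag in −3..3 and
checks that the scan's peak lands on the injected lag; we run 200
replicates per lag on 200-day windows with 150 comments/day — sizes chosen
so each replicate's negative-emotion count (~25/day) carries enough
day-to-day Poisson variability to identify the lag while the whole
experiment stays desk-sized. The experiment sets `emotion_case_coupling`
to 0: an undetrended cross-correlation cannot localize a lag between two
series dominated by one smooth epidemic trend (neighbouring lags correlate
almost equally), and this pipeline — by design — applies no detrending. The
stationary-stream experiment isolates exactly the question the scan can
answer: given day-scale variation, is the injected lead/lag found? Under
these conditions recovery is essentially certain (≥ 95% per lag).

`null_false_alarm_experiment()` repeats the run with coupling 0 and reports
the fraction of replicates significant at one fixed lag — the per-lag level,
about 5% — alongside the family-wise rate across all 21 lags, about 66%, to
make the uncorrected-scan caveat concrete.

## Limitations

* The calibration assumes the post-change clinical/nucleic ratio also held
  pre-change; with only two ratio days the multiplier inherits their noise.
* Lag identification on strongly trending, undetrended series is
  fundamentally weak; peaks on short windows (~50 days) with smooth trends
  should be read cautiously, significant or not.
* Correlation at a lag is not causation in either direction; the package
  deliberately offers no Granger or transfer-entropy machinery.
* The coding module aggregates labels; it neither classifies text nor
  models coder covariance.
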