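---
title: "Wood lactation curves, truncated-lactation projection and culling accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wood lactation curves, truncated-lactation projection and culling accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactwood)
```

## The model and its assumptions

A lactation curve tracks a milk trait over days in milk (DIM). lactwood
uses Wood's gamma-type model,

$$y(x) = a\,x^{b}\,e^{-c x},$$

with $x$ DIM and $y$ the trait value on a test day. The three parameters
have direct interpretations: $a$ is a scale in trait units, $b$ (dimensionless)
the steepness of the pre-peak rise, $c$ (per day) the post-peak decline.
When $b, c > 0$ the curve peaks at day $b/c$ with value $a (b/c)^b e^{-b}$;
when either is non-positive the curve is monotone over $x > 0$ and
`wood_peak()` reports that no interior peak exists. This matters in
practice: fits to short truncated windows, where the herd is still on the
rising limb, genuinely produce $c < 0$, so no positivity constraint is
imposed on $b$ or $c$ anywhere in the package.

Cumulative yield over $[t_0, t_1]$ is the definite integral of the curve.
For $c > 0$ it has the closed form
$a c^{-(b+1)}[\gamma(b+1, c t_1) - \gamma(b+1, c t_0)]$ with $\gamma$ the
lower incomplete gamma function (computed via `pgamma`); for $c \le 0$
(where the incomplete gamma with negative argument is not generally
available) adaptive quadrature is used, with absolute tolerance $10^{-6}$
kg and relative tolerance $10^{-10}$. A property test drives both routes
over a thousand random parameter draws and requires agreement to
$10^{-8}$ relative.

Integrals may start at calving ($t_0 = 0$): the integrand's singularity in
slope at the origin is integrable whenever $b > -1$, and the package
rejects $b \le -1$ with an explicit divergent-integral error rather than
returning a spurious number.

The model assumes a single smooth unimodal (or monotone) trajectory per
group — no oestrus dips, disease events, seasonality or pregnancy effects.
Days in milk are 1-based integers in records (first milking day = 1);
curve evaluation itself accepts any positive real day.

## Fitting

`fit_wood()` minimises $\sum_i (y_i - a x_i^b e^{-c x_i})^2$ on the
natural scale by Levenberg–Marquardt (via minpack.lm), initialised from
the classical log-linearisation $\ln y = \ln a + b \ln x - c x$
(`fit_loglinear()`, ordinary least squares, exact interpolation at three
distinct days). Design choices:

* **Why natural-scale nls as the default.** The log-linearisation
  minimises multiplicative error and is biased for the level of the curve
  under noise; the natural-scale fit matches the quantity the analysis
  integrates (kg). Both are exposed through `method = "nls" | "loglinear"`
  since either convention is defensible on test-day data.
* **Positivity of $a$ only.** The optimiser works on $\ln a$ internally,
  keeping the scale positive without a box constraint; $b$ and $c$ are
  free in sign (see above).
* **Convergence.** Relative-SSE tolerance $10^{-10}$, at most 500
  iterations, so fits reproduce across platforms at printed precision. If
  the refinement fails the log-linear parameters are returned with
  `converged = FALSE`, and the refined fit is never allowed to report a
  higher residual sum of squares than its initialiser.
* **Determinism.** Records are put in a canonical (day, value) order
  before any fit, so results are exactly invariant to input row order.
* **Non-positive trait values** are dropped from the log-linear step (with
  a count kept on the fit object) but retained for the nonlinear step,
  which needs no logarithms.
* **No weighting** by cow or test count: herd-level curves are fitted to
  the pooled test-day records of all cows in scope. Per-cow and per-cohort
  fitting reuse the identical machinery.
* **At least three distinct days** are required (three parameters);
  degenerate inputs fail with an insufficient-data error.

`fit_truncated()` fits only records up to a truncation day and integrates
the fitted curve over both the truncated window (modelled actual yield)
and $[0, 305]$ (projected full-lactation yield). `truncation_series()`
tabulates this over a grid of truncation days (default 30, 60, …, 270,
305). On synthetic herds with known ground truth the projection error at
truncation 270 is far below that at truncation 30 — the accuracy of the
projection grows with days in milk — though the series need not be
monotone in between, since early windows barely identify $b$ and $c$.

## Culling accounting

Cohort membership follows the count of monthly tests a cow attended: a cow
with $k$ tests lands in the $0\!-\!30k$ cohort, and cows with at least
$\lfloor 305/30 \rfloor = 10$ tests are completers. This makes each
cohort's milkings/cows ratio exactly its test count, the structure routine
milk-recording summaries exhibit.

The counterfactual herd average — what the herd would have produced had no
cow been culled — is the cow-number-weighted mean of the cohorts'
projected 305-day yields; the per-cow culling gain is the realised average
minus that counterfactual, sign preserved (culling that removed
above-average cows would show a negative gain).

**Identifiability and shape-borrowing.** A cohort culled before the herd's
peak (final day 30–90 when the peak sits near day 105) has records only on
the rising limb: a free three-parameter fit extrapolated tenfold is poorly
identified. `build_culling_report()` therefore borrows the completer
cohort's fitted $b$ and $c$ for cohorts with `final_day <= borrow_max_day`
(default 90 — windows ending before a typical peak) or with fewer than
three distinct pooled test days, and rescales $a$ by the cohort's mean
observed-to-herd-curve ratio. This "shape-borrowing" reflects the view
that early-lactation heterogeneity is mostly in level, not shape; it is a
package design choice for regimes where the data cannot speak, not a
claim about how any particular published analysis achieved
identifiability. Free fits remain available (`borrow_max_day = 0`), and on
synthetic herds both variants land within a few percent of the ground-truth
mean, with the borrowed version markedly closer.

When a published cohort table already carries projected yields,
`culling_report_from_cohorts()` performs the accounting with no fitting at
all; the bundled herd-T1 table reproduces its counterfactual (9798.13 kg)
and gain (1586.87 kg) to the printed decimals. The realised herd average
(11,385 kg for that herd) is an input in this mode; in simulation it is
the completers' realised mean.

**Rounded reference parameters.** The bundled truncation-fit table prints
parameters to four decimals ($c$ to two significant figures in places), so
re-integrating the printed parameters reproduces the printed areas only
approximately; the validation suite checks agreement at 3% relative rather
than equality, and the package treats the printed areas as computed from
unrounded fits.

## Curve comparison

`compare_curves()` runs the tie-corrected Kruskal–Wallis omnibus test
(chi-square approximation, $k-1$ df, mid-ranks for ties; identical values
across all groups return $H = 0$, $p = 1$) and Dunn's pairwise z-tests,

$$z_{ij} = \frac{\bar R_i - \bar R_j}
  {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum(t^3 - t)}{12(N-1)}\right)
  \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},$$

with two-sided normal $p$-values and Holm–Šidák step-down adjustment
($p^{adj}_{(i)} = \max_{j \le i}[1 - (1 - p_{(j)})^{m-j+1}]$, clipped to
1). Design choices:

* The default comparison sample is each group's fitted curve evaluated at
  integer days 1…305. Sampling a smooth curve densely pseudo-replicates
  it — the effective information is three parameters per curve, not 305
  points — so the printed report carries that caveat and the resulting
  $p$-values should be read as descriptive, not confirmatory.
* Two-sided Dunn tests, the field default.
* No normality pre-test gates the pipeline: the analysis always runs the
  rank-based tests, keeping behaviour deterministic rather than
  conditioning the test choice on a Shapiro–Wilk outcome.

Calibration is tested: over 2000 null replicates (three groups of 305
standard normals) the omnibus rejection rate at $\alpha = 0.05$ must lie
in $[0.04, 0.06]$, and the chi-square $p$ is compared against the exact
permutation null at small group sizes, where the approximation is known
to be coarse (agreement asserted at the 0.15 level there).

## The synthetic herd generator

`simulate_herd()` emulates the statistical structure the analysis assumes,
so every stage is testable without external data. Defaults describe the
study conditions the package targets — a large high-yield primiparous
herd under monthly recording:

* 628 cows; herd milk curve $a = 13.7833$, $b = 0.3056$, $c = 0.0029$
  (peak near day 105 at ~42 kg/day).
* Per-cow heterogeneity mainly in level: a lognormal multiplier on $a$
  with CV 0.15, plus mild additive jitter on $b$ and $c$ (sd 10% of each).
  This keeps per-cow peak days clustered near the herd's, consistent with
  a single herd-level shape.
* Monthly tests: first test uniform on days 5–35, subsequent intervals
  30 ± 3 days (uniform); an uninterrupted lactation attends the full ten
  tests within 305 days, so cohort milkings/cows ratios come out exactly
  integral, as in recording-scheme summaries.
* Multiplicative lognormal residual noise, CV 0.08 per record (yields are
  positive and their dispersion grows with level; no residual model is
  standard, so this is a package choice).
* Threshold culling: at each of the first three tests, a cow whose
  *observed* (noisy) milk record falls strictly below 24 kg stops being
  recorded, mirroring field practice of acting on the measured test-day
  yield. Note that with first tests as early as day 5, part of the culled
  group is low simply for being tested very early in the rise — selection
  on the observed record, not on true merit, exactly as a fixed-threshold
  rule behaves.
* Composition traits (fat, protein, lactose, urea) reuse the same
  machinery with their own Wood parameters, chosen to sketch the usual
  shapes (early fat/protein dip, near-flat lactose, urea tracking the
  milk curve); no quantitative claims attach to them.
* Determinism: the herd is a pure function of the configuration including
  its seed; per-cow streams are derived from the master seed.

Ground truth (each cow's true parameters, true 0–305 integral and culling
day) is returned alongside the records for oracle checks. What the
generator does **not** emulate: pregnancy and dry-off, seasonality and
test-date sharing across cows, parities beyond the first, disease events,
and culling for reasons other than low yield — so cohorts at intermediate
final days (120–270) arise in real data but not under the default
configuration. Passing tests on synthetic herds demonstrate the
pipeline's internal consistency under the stated noise model, not its
adequacy for any particular real herd.

## Problem sizes and tolerances in the test suite

The suites run at sizes chosen to make the statistical assertions sharp
while keeping a full run around a minute: 1000 parameter draws for the
integral-equivalence property ($10^{-8}$ relative); zero-noise recovery to
$10^{-6}$ and noisy recovery as a sub-5% median relative error over
20 replicates of 200-cow herds; culling-gain positivity over 100 seeds of
150-cow herds (and exact zero, to $10^{-9}$, with culling disabled); 2000
null replicates for omnibus calibration; and the step-down adjustment
against hand-computed values. The round-trip simulate → fit → report check
asserts the counterfactual within 3% of the ground-truth mean at default
noise.

## Known limitations

* Point fits only: no standard errors or confidence intervals on
  parameters, peaks or projected yields.
* Alternative lactation models (Ali–Schaeffer, Wilmink) and persistence
  indices beyond phase shares are out of scope.
* The curve-comparison module inherits the pseudo-replication caveat
  above; its $p$-values depend on the chosen day grid.
* Economic consequences of culling (rearing cost, replacement value) are
  not modelled; the accounting is purely in kg of milk per cow.
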