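# lactwood

Lactation-curve analysis for dairy herds: Wood-model fitting to monthly
test-day records, peak and cumulative-yield computation, 305-day yield
projection from truncated lactations, culling-impact accounting on the herd
average, and nonparametric comparison of lactation curves. Written for
animal scientists and herd analysts working with routine milk-recording
data for primiparous (first-lactation) cows.

## The model

Daily yield over a lactation is described by Wood's gamma-type function

    y = a · x^b · e^(−c·x)

where `x` is days in milk (DIM), `y` the trait value on the test day (milk
kg/day; fat, protein, lactose %; milk urea mg/L), `a` scales the curve,
`b` governs the pre-peak rise and `c` the post-peak decline. For `b, c > 0`
the curve peaks at day `b/c` with yield `a·(b/c)^b·e^(−b)`; negative `c`
(a curve still rising at the window's end, common in fits to short
truncated lactations) is fully supported. Cumulative yield over an interval
is the definite integral of the curve, evaluated through the lower
incomplete gamma function for `c > 0` and by adaptive quadrature otherwise:

    ∫ₜ₀^ₜ₁ a·x^b·e^(−c·x) dx = a·c^−(b+1)·[γ(b+1, c·t1) − γ(b+1, c·t0)]

Fitting is nonlinear least squares on the natural scale
(Levenberg–Marquardt), initialised from the classical log-linearisation
`ln y = ln a + b·ln x − c·x`.

The culling accounting asks what a herd's 305-day average would have been
had no cow been culled early: each cohort of cows sharing a final milking
period gets a Wood curve on its truncated records, extended to 305 days,
and the counterfactual herd average is the cow-number-weighted mean of the
cohorts' projected yields. The difference between the realised average and
that counterfactual is the per-cow yield gain attributable to culling.

Curve comparisons use the Kruskal–Wallis rank test with Dunn's pairwise
post-hoc z-tests under Holm–Šidák step-down adjustment.

## Worked example

The full-lactation herd curve of a high-yield primiparous herd
("herd T1": a = 13.7833, b = 0.3056, c = 0.0029, bundled in
`herd_t1_wood_params()`):

```r
library(lactwood)
p <- wood_params(13.7833, 0.3056, 0.0029, trait = "milk")
wood_peak(p)
#> Lactation peak: day 105.38 (day 105), value 42.149
wood_cumulative(p, 0, 305)
#> [1] 11542.6
round(phase_shares(p, c(100, 200), 305), 3)
#>   0-100d 100-200d 200-305d
#>    0.318    0.355    0.327
```

The herd peaks on day 105 at about 42.1 kg/day; mid-lactation
(days 100–200) contributes 35.5% of the 305-day total — a flat, persistent
curve. (The 11,542.6 kg integral differs from the bundled table's 11,367.83
by 1.5%: the table's areas were computed from unrounded parameters, while
the printed parameters carry four decimals.)

Culling-impact accounting from the herd's published cohort table
(`herd_t1_cohorts()`, 628 first lactations, 24 kg culling criterion), with
its realised 305-day average of 11,385 kg:

```r
culling_report_from_cohorts(herd_t1_cohorts(), herd_t1_actual_yield)
#> Culling-impact report
#>   cohorts: 10 | cows: 628 | milkings: 3427
#>   realised herd 305-d average (with culling):   11385.00 kg
#>   counterfactual average (no culling):           9798.13 kg
#>   gain per cow attributable to culling:          1586.87 kg
```

Had the culled low producers been milked to 305 days the herd average
would have been 9798.13 kg; culling them raised it by 1586.87 kg per cow.

The same pipeline runs end to end on synthetic herds with known ground
truth:

```r
herd <- simulate_herd(herd_sim_config(n_cows = 200, seed = 42))
fit_wood(herd$records)
#> Wood fit (milk, nls): n = 1748 over days [5, 305]
#>   a = 12.8892, b = 0.3305, c = 0.0030 | rss = 1.287e+05 | converged: TRUE
build_culling_report(herd$records)
#> Culling-impact report
#>   cohorts: 2 | cows: 200 | milkings: 1748
#>   realised herd 305-d average (with culling):   12042.73 kg
#>   counterfactual average (no culling):          11639.62 kg
#>   gain per cow attributable to culling:           403.11 kg
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/lactwood` (subcommands `simulate`, `fit`, `predict`,
`culling-impact`, `compare`, `report`; see `?cli_main`).

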