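# futilitymon

Interim **futility monitoring** for randomized clinical trials, on the
Brownian-motion (B-value) scale.

Data monitoring committees face two questions at an interim analysis:
*is a null result likely?* and *would a null result still be meaningful?*
`futilitymon` implements the standard quantitative toolkit for both, for
statisticians designing or monitoring group-sequential trials:

* **Conditional power (CP)** under the design hypothesis, the current trend
  `B(t)/t`, or any assumed drift; **reverse conditional power (RCP)**, which
  needs no treatment-effect assumption; **predictive probability of success
  (PPoS)** under a normal prior on the drift.
* **Operating characteristics of stochastic-curtailment rules** ("stop if
  CP ≤ Γ"), computed exactly by recursive numerical integration — including
  how badly current-trend curtailment erodes power and how little
  RCP-based curtailment costs.
* **Alpha- and beta-spending boundaries** (O'Brien–Fleming-like and
  Hwang–Shih–DeCani families) with the coupled futility-boundary + drift
  calibration, giving the sample-size price of aggressive beta spending.
* **Predicted intervals and predicted-interval plots (PIP)** for binary and
  survival endpoints: simulate the unobserved remainder of the trial under
  stated assumptions and summarize the end-of-trial confidence intervals.
* **Design helpers**: endpoint summaries → drift, revised unconditional
  power, inefficacy-monitoring rules, and a Monte-Carlo path simulator that
  serves as an independent oracle for every probability the engine computes.

## The model in one paragraph

Indexed by information fraction `t = I/I_end` (sample-size or event-count
ratio), the interim z-scores of a two-arm trial satisfy
`B(t) = √t·Z(t) ~ N(θt, t)` with independent increments, where the drift
`θ = E[Z(1)]` is the expected final z-score (`θ = z_crit + qnorm(power)`;
e.g. 3.24 for 90% power at one-sided α = 0.025). Conditional power is
`Φ((b + θ(1−t) − z_crit)/√(1−t))`; reverse conditional power is
`Φ((z√t − z_crit·t)/√(t(1−t)))`; boundary and operating-characteristic
calculations integrate this process over the look schedule. Positive
z-scores favor treatment throughout (`θ = −log(HR)·√(D/4)` for a 1:1
survival trial with `D` target events).

## Worked example

A survival trial targeting 713 events has 90% power for HR 0.78. At an
interim analysis with 346 events (`t = 0.485`) the benefit-positive logrank
z-score is 0.733:

```r
library(futilitymon)

s <- interim_state(t = information_fraction(346, 713), z = 0.733)
conditional_power(s, theta = drift_from_power(0.90))
#> # A tibble: 1 × 4
#>       t     z     b    cp
#>   <dbl> <dbl> <dbl> <dbl>
#> 1 0.485 0.733 0.511 0.620
reverse_conditional_power(s)
#> # A tibble: 1 × 4
#>       t     z     b   rcp
#>   <dbl> <dbl> <dbl> <dbl>
#> 1 0.485 0.733 0.511 0.189
```

Under the design hypothesis this trial still has conditional power 0.620 —
nowhere near a futility threshold of 0.20 — and the RCP of 0.189 says that
among trials ending barely significant, 19% would look at least this
unpromising at the interim. Neither supports stopping, even though the
*current-trend* conditional power at this interim was near 0.10. How
dangerous is curtailing on the current trend? Exactly this dangerous:

```r
oc <- futility_oc(futility_rule("cp_current_trend", 0.20),
                  times = c(seq(0.1, 0.7, by = 0.1), 1), power = 0.90)
glance(oc)
#> # A tibble: 1 × 7
#>   kind             threshold n_looks theta type2_error p_fail_final power
#>   <chr>                <dbl>   <int> <dbl>       <dbl>        <dbl> <dbl>
#> 1 cp_current_trend       0.2       8  3.24       0.396       0.0197 0.604
```

A 90%-power design monitored this way has true power 0.60 — type II error
≈ 0.40 instead of 0.10. (The same threshold applied to CP under the
*original* hypothesis gives ≈ 0.103.) A pre-specified beta-spending design
is the disciplined alternative:

```r
des <- gs_futility_design(c(0.25, 0.5, 0.75, 1),
                          beta_spec = spending("hsd", 0.15, gamma = -4))
des
#> <gs_design> 4 looks, calibrated drift = 3.0573 (power 0.850 at the final test)
#> # A tibble: 4 × 6
#>    look     t  lower_z upper_z cum_beta_spent cum_alpha_spent
#>   <int> <dbl>    <dbl>   <dbl>          <dbl>           <dbl>
#> 1     1  0.25 -1.06       4.33        0.00481      0.00000737
#> 2     2  0.5  -0.00369    2.96        0.0179       0.00153   
#> 3     3  0.75  0.976      2.36        0.0534       0.00965   
#> 4     4  1     2.01       2.01        0.150        0.0250
```

Stop for futility at the first look only below z = −1.06; the final
boundaries meet at 2.014 so the trial ends with a verdict. The conservative
`gamma = -4` spending needs drift 3.057, barely above the 3.00 a
no-monitoring 85%-power design requires; `gamma = +2` needs 3.535, i.e.
`(3.535/3.057)² ≈ 1.34` — a 34% larger sample size.

`autoplot()` methods draw boundaries, spending functions, and
predicted-interval plots; `tidy()`/`glance()` return tibbles throughout. A
command-line front end wrapping the same functions ships in
`inst/cli/futility.R` (subcommands `cp`, `rcp`, `ppos`, `boundaries`,
`curtailment-oc`, `pip`, `design-power`, `freidlin-t0`, `inefficacy-check`,
`simulate`; JSON/CSV output).

See the vignette (`vignettes/futility-monitoring.Rmd`) for the model,
numerical choices, and design decisions.

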