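---
title: "Futility monitoring on the B-value scale: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Futility monitoring on the B-value scale: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(futilitymon)
library(dplyr)
```

## The monitoring model

All of `futilitymon` rests on one approximation: for a two-arm randomized
trial with a continuous, binary, or survival endpoint, the sequence of
interim test statistics behaves like a Brownian motion with drift when
indexed by *information time*. Information is the inverse variance of the
effect estimate; the information fraction `t = I / I_end` is well
approximated by the sample-size ratio (non-survival) or the event-count
ratio (survival). Writing `Z(t)` for the interim z-score (positive values
favoring treatment) and `B(t) = sqrt(t) * Z(t)` for the B-value, the model
says:

* `B(t) ~ N(theta * t, t)` and `Z(t) ~ N(theta * sqrt(t), 1)`,
* increments `B(t2) - B(t1) ~ N(theta * (t2 - t1), t2 - t1)` are independent
  of the past,
* `cov(Z(t1), Z(t2)) = sqrt(t1 / t2)`.

The *drift* `theta = E[Z(1)]` is the expected final z-score. It links the
design to the monitoring process: a one-sided level-`alpha` design with
power `1 - beta` has `theta = z_crit + qnorm(power)`, e.g. 2.80, 3.00 and
3.24 for 80%, 85% and 90% power at `z_crit = 1.96`. Endpoint summaries map
to drifts in `drift_from_endpoint()`: `delta * sqrt(I_end)` for mean or
proportion differences, and `-log(HR) * sqrt(D/4)` (1:1 allocation, `D`
target events) or `-log(HR) * sqrt(2D/9)` (2:1) for hazard ratios, so
benefit (HR < 1) is a positive drift.

Everything downstream is an exercise in normal conditioning or in numerical
integration of this process over a discrete look schedule.

## Closed-form interim statistics

**Conditional power** is the probability of final significance given the
interim data and an assumed drift,

$$CP = \Phi\!\left(\frac{b + \theta(1-t) - z_{crit}}{\sqrt{1-t}}\right),$$

computed under the originally hypothesized drift, the current trend
`theta = B(t)/t`, or anything between. We deliberately make `t = 1` an
error rather than returning 0/1: at the end of the trial the caller should
compare `Z(1)` to the critical value directly, and a silent division by
`sqrt(1 - t)` would mask that.

**Reverse conditional power** conditions the other way around — on a barely
significant final result — and asks how probable interim results at least
this disappointing would be:

$$RCP = \Phi\!\left(\frac{z\sqrt{t} - z_{crit}\,t}{\sqrt{t(1-t)}}\right).$$

Because `Z(1)` is sufficient for the drift, RCP involves no treatment-effect
assumption at all; that is its selling point, and the operating
characteristics below quantify it.

**Predictive probability of success** (`ppos()`) averages conditional power
over the posterior of the drift under a normal prior
`theta ~ N(theta0, sigma0_sq)`. At `sigma0_sq = 0` it reduces *exactly* to
conditional power at `theta0` (a property the tests assert to 1e-12); as the
prior widens it moves toward conditional power under the observed trend.

```{r closed-forms}
s <- interim_state(t = 0.5, z = 0.3)
conditional_power(s, theta = drift_from_power(0.85))
reverse_conditional_power(s)
ppos(s, theta0 = 3, sigma0_sq = 1)
```

### Sign and critical-value conventions

Positive z-scores favor treatment everywhere, so for hazard ratios the
package uses `theta = -log(HR) * sqrt(D/4)`. The critical value defaults to
the conventional rounded `1.96` rather than `qnorm(0.975)`; every function
accepts `z_crit` to override. The two differ by 3.6e-5, which is invisible
at the 2–3 decimals monitoring reports use, but it does mean that e.g. the
reverse-curtailment trigger at `t = 0.5` sits at `z = 2.5e-5` rather than
exactly 0 unless `z_crit = qnorm(0.975)` is requested.

## Operating characteristics of curtailment rules

A stochastic-curtailment guideline stops for futility when CP (or RCP)
falls to a threshold `Gamma` or below; ties stop. Under continuous
monitoring of CP under the *original* hypothesis, the type II error rate is
bounded by `beta / (1 - Gamma)` (`continuous_curtailment_beta()`); no such
bound protects CP under the *current trend*, which is exactly the trap the
operating-characteristics machinery quantifies.

`futility_oc()` evaluates a rule exactly rather than by simulation: each
rule is inverted in closed form into per-look z thresholds
(`rule_thresholds()`), and the stop-or-fail probability under the design
drift is computed by the recursive integration engine. A "K-look" design
means analyses at `t = j/K` with futility assessed at the `K - 1` interims
and the final test at `z_crit`; with `K = 1` the type II error is `beta`
exactly, which pins down this reading of "number of looks". There is no
interim efficacy stopping in these evaluations (pure futility guidelines),
though `futility_oc(upper = ...)` accepts efficacy bounds for combined
designs.

```{r oc}
oc_table(futility_rule("cp_current_trend", 0.20),
         powers = c(0.80, 0.85, 0.90), n_looks = 1:6) |>
  tidyr::pivot_wider(names_from = n_looks, values_from = type2_error) |>
  mutate(across(-power, ~ round(.x, 3)))
oc_table(futility_rule("rcp", 0.025),
         powers = c(0.80, 0.85, 0.90), n_looks = 1:6) |>
  tidyr::pivot_wider(names_from = n_looks, values_from = type2_error) |>
  mutate(across(-power, ~ round(.x, 3)))
```

The first table shows the current-trend rule eroding a 90%-power design to
type II error 0.306 at six looks; the RCP-0.025 rule (second table) costs
almost nothing. With a dense early schedule (looks at 10%–70% information
plus the final analysis) the current-trend rule's type II error reaches
about 0.40 — four times the design level — while the same threshold under
the original hypothesis stays near 0.103.

## The group-sequential engine

First-crossing probabilities for a discretely observed Brownian motion are
computed by the classical sub-density recursion, implemented on the z-score
scale because boundaries are stated as z-scores. The density of paths that
have not yet stopped is tabulated on Gauss–Legendre nodes over each look's
continuation region; transitions use the conditional normal increment law.
Numerical choices, fixed once:

* 301 nodes per look interval, integration truncated at the marginal mean
  ± 8 (the z-scale standard deviation is 1) intersected with the
  continuation region. The integrand is smooth inside that region, so
  Gauss–Legendre converges spectrally; total-mass conservation holds to
  ~1e-10 and results are stable to far fewer nodes.
* Boundary root-finding by `uniroot` at tolerance 1e-12; drift calibration
  by bisection to 1e-8. All deterministic — no seeds anywhere in the
  engine.
* `±Inf` boundaries are first-class sentinels for "no boundary on this
  side"; a look with `lower == upper` (the final analysis of a futility
  design) splits all remaining mass.

**Efficacy boundaries** (`alpha_boundaries()`) are solved look by look under
zero drift so the upper first-crossing probabilities match the alpha
spending increments, *ignoring* any futility boundary. This non-binding
convention is deliberate: deriving efficacy bounds that assume the futility
guideline will be obeyed would let a continued trial exceed the type I
error rate, and futility guidelines are routinely overridden in practice.

**Futility boundaries** (`gs_futility_design()`) respect the efficacy
bounds, as a type II error requires crossing the lower boundary without
having first crossed the upper one. For each candidate drift, the interim
lower boundaries are solved against the beta-spending increments; the final
lower boundary is tied to the final upper boundary so the trial ends with
an unambiguous verdict; the drift is then calibrated so the total type II
error equals the beta to be spent (total type II is monotone decreasing in
the drift, so bisection suffices where a grid search would also do). A
spending increment larger than the mass available below the efficacy bound
is clamped to the efficacy boundary with a warning — the signature of
over-aggressive spending.

```{r design}
des <- gs_futility_design(c(0.25, 0.5, 0.75, 1),
                          beta_spec = spending("hsd", 0.15, gamma = -4))
tidy(des)
glance(des)
```

Spending families provided: O'Brien–Fleming-like
`2 * (1 - pnorm(qnorm(1 - total/2) / sqrt(t)))` — very conservative for
alpha-sized totals, noticeably less so for beta-sized ones — and the
Hwang–Shih–DeCani gamma family, with `gamma = 0` defined by its linear
limit `total * t` (a removable singularity in the printed formula). The
squared ratio of two calibrated drifts is the relative sample size the two
spending attitudes imply; conservative spending (`gamma = -4`) costs almost
nothing over a no-monitoring design (drift 3.057 vs 3.00 for 85% power),
while aggressive spending (`gamma = +2`, drift 3.535) inflates the sample
size by about 34%.

A note on reproducibility of published boundary tables: a solver of this
kind reported to four decimals carries the author's grid resolution. Our
bisection at 1e-8 agrees with widely circulated four-look values to within
one unit in the fourth decimal on every boundary and about 1.4e-4 on the
calibrated drifts, consistent with a reference drift grid of step 1e-4.

## Predicted intervals and PIP

Predicted intervals answer an estimation question rather than a testing
one: if the trial ran to completion under stated assumptions about the
unobserved data, what confidence interval would we report? For a binary
endpoint the unobserved remainder of each arm is drawn
`Binomial(N - n, pi)`, pooled with the observed counts, and the Wald
interval formed at the target sizes. We report the intervention-minus-
control difference `p_i - p_c`, so event reduction is negative and the
null line sits at 0. For survival endpoints we skip event-time modelling
entirely and simulate the final statistic directly from the increment law,
`Z(1) = b + theta(1 - t) + N(0, sqrt(1 - t))`, back-transforming interval
limits to the hazard-ratio scale through the allocation-specific drift
relation.

`pip()` repeats this `M` times (500 is plenty for a plot; 1e4 gives stable
medians), groups replicates by centrality, and summarizes with the
replicate at the median or — under `grouping = "cpdf_mode"` — at the mode
of a Gaussian-kernel density estimate (normal-reference bandwidth) of the
point-estimate distribution. Percentile grouping uses four brightness bands
at the 50/80/95/100 central shells; the band count is a display choice, not
a statistical one.

```{r pip}
st <- binary_trial_state(N_c = 1212, N_i = 1212, n_c = 606, n_i = 606,
                         x_c = 123, x_i = 90, pi_c = 0.2, pi_i = 0.2)
p <- pip(st, M = 2000, seed = 1)
glance(p)
binary_observed_interval(st)
```

Against the half-information interim interval, the predicted interval is
about 27%–29% narrower (`interval_width_reduction()`): completing the trial
buys roughly the `sqrt(2)` precision gain the information ratio implies.
Two cautions when comparing medians of PIP runs: a median of `M`
replicates has Monte-Carlo standard error about `1.2533 * sd / sqrt(M)`,
so two runs at different `M` (or different seeds) should be compared at
their *combined* standard errors plus any rounding of the reported digits;
and under an assumption that contradicts the observed trend the median is
*supposed* to be attenuated toward the assumption — that is the
sensitivity-analysis point of the plot, not a bias.

## Design-stage helpers

`revised_power()` addresses the second futility question — would a null
result still be meaningful? It recomputes `pnorm(theta - z_crit)` from a
drift rebuilt with interim-updated nuisance parameters (event rates,
variances) via `drift_from_endpoint()`, keeping the two steps explicit. Low
conditional power with *high* revised power argues for continuing (a
reliable null answer is still coming); low on both argues for stopping.

Inefficacy monitoring (`inefficacy_check()`) starts at
`t0 = (qnorm(0.975) / (z_alpha + z_beta))^2` — the time from which a
wrong-direction z-score implies the nominal 95% interval excludes the
design effect (`t0 = 0.366` for a one-sided 0.025, 90%-power design).
Strategy 1 stops on any `z < 0` after `t0`; strategy 2 stops when the
nominal interval on the drift scale, `(z ± qnorm(0.975)) / sqrt(t)`, lies
entirely below the design drift (at `t0` this coincides with `z < 0`);
strategy 3's sliding scale is under-determined in the literature, and we
implement one concrete reading — the drift that must be excluded shrinks
linearly from `theta` at `t0` to 0 at `t = 1`, so late stopping requires
increasingly extreme results — with the exclusion target recorded in the
output. The single-look rule "more events on treatment than control at
half the events" is strategy 1 with `t0 = 0.5`.

## The simulator, and what passing tests do and do not show

`simulate_paths()` is the package's independent oracle: B-value paths built
from independent normal increments, never through the integration engine.
Every deterministic probability in the engine has a Monte-Carlo twin test
at 2e5 paths and a 3-standard-error gate; the simulator itself is checked
against the closed-form marginal moments and the `sqrt(t1/t2)` correlation
structure. `simulate_binary_trial()` generates interim binary-trial states
with Binomial counts at the interim sizes.

The generator emulates exactly the idealized model above: exact normality,
exact information fractions, a drift constant over information time, no
overrunning between decision and stop, and independent increments. Real
trials violate all of these to some degree — staggered entry with delayed
endpoint ascertainment, drifts that move when early hazards are
non-proportional, information fractions estimated from nuisance parameters,
and endpoint misclassification at interim review (investigator-assessed
versus adjudicated outcomes can reverse a futility verdict). Passing tests
therefore certify the *computations under the Brownian model*, not the
model's fit to any particular trial; the dense-early-look results above are
themselves a demonstration of how fragile current-trend extrapolation is
even *within* the model.

Problem sizes used throughout the test suite — 2e5 simulated paths for
oracle comparisons, 1e4 PIP replicates for median checks, schedules of up
to eight looks — were chosen so every Monte-Carlo gate has comfortable
power to detect a real defect while the whole suite runs in well under a
minute.

## Known limitations

* Everything lives on the canonical Brownian scale; there are no exact
  binomial or survival-specific group-sequential computations, and no
  repeated-confidence-interval or stage-wise-ordering inference after
  stopping.
* Continuous-endpoint predicted intervals are not implemented (the binary
  machinery generalizes directly; the survival path covers the B-value
  shortcut).
* Type I error of futility rules is not tabulated — futility stopping can
  only decrease it, and recovering that "lost" alpha by relaxing efficacy
  bounds is a practice we deliberately do not support.
* The posterior-probability style of Bayesian futility (stop when the
  posterior probability of a meaningful effect is small) is out of scope;
  only the normal-prior predictive probability of success is provided.
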