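#' Drift parameter from an endpoint summary
#'
#' Translates a design-stage (or interim-revised) endpoint summary into the
#' drift parameter, the expected final z-score. For continuous and binary
#' endpoints `theta = delta * sqrt(I_end)` with `I_end` the inverse variance
#' of the effect estimate at the final sample sizes; for survival endpoints
#' `theta = -log(HR) * sqrt(D / 4)` (1:1 allocation) or
#' `-log(HR) * sqrt(2 * D / 9)` (2:1), benefit-positive.
#'
#' @param kind `"continuous"`, `"binary"` or `"survival"`.
#' @param ... Passed to the endpoint-specific helper: [drift_continuous()],
#'   [drift_binary()] or [drift_survival()].
#' @return A drift value.
#' @examples
#' drift_from_endpoint("survival", hr = 0.78, events = 713)
#' @export
drift_from_endpoint <- function(kind = c("continuous", "binary", "survival"),
                                ...) {
  switch(match.arg(kind),
    continuous = drift_continuous(...),
    binary = drift_binary(...),
    survival = drift_survival(...)
  )
}

#' @rdname drift_from_endpoint
#' @param delta Mean difference (benefit-positive).
#' @param sd Common outcome standard deviation.
#' @param n_c,n_i Final per-arm sample sizes.
#' @export
drift_continuous <- function(delta, sd, n_c, n_i = n_c) {
  if (sd <= 0 || n_c <= 0 || n_i <= 0) {
    abort_domain("`sd` and sample sizes must be positive.")
  }
  delta / (sd * sqrt(1 / n_c + 1 / n_i))
}

#' @rdname drift_from_endpoint
#' @param p_c,p_i Event probabilities in the control and intervention arms;
#'   the effect is the reduction `p_c - p_i`, so fewer events under treatment
#'   gives a positive drift.
#' @export
drift_binary <- function(p_c, p_i, n_c, n_i = n_c) {
  check_prob(p_c, "p_c")
  check_prob(p_i, "p_i")
  if (n_c <= 0 || n_i <= 0) abort_domain("Sample sizes must be positive.")
  v <- p_c * (1 - p_c) / n_c + p_i * (1 - p_i) / n_i
  if (v <= 0) abort_domain("Zero variance: degenerate event probabilities.")
  (p_c - p_i) / sqrt(v)
}

#' @rdname drift_from_endpoint
#' @param hr Hazard ratio (< 1 means benefit).
#' @param events Target total number of events `D`.
#' @param allocation `"1:1"` or `"2:1"` randomization.
#' @export
drift_survival <- function(hr, events, allocation = c("1:1", "2:1")) {
  allocation <- match.arg(allocation)
  if (hr <= 0) abort_domain("`hr` must be positive.")
  if (events <= 0) abort_domain("`events` must be positive.")
  cc <- if (allocation == "1:1") sqrt(events / 4) else sqrt(2 * events / 9)
  -log(hr) * cc
}

#' Revised unconditional power
#'
#' Re-does the design power calculation with a drift computed from
#' interim-updated nuisance parameters (event rates, outcome variance):
#' `pnorm(theta_revised - z_crit)`. Low conditional power says a null result
#' is likely; low revised power says even that null result would not answer
#' the trial's question — the combination is the strongest case for stopping.
#'
#' @param theta_revised Drift recomputed from revised nuisance parameters,
#'   e.g. via [drift_from_endpoint()].
#' @param z_crit Critical value for the final test; defaults to 1.96.
#' @return The revised power.
#' @examples
#' revised_power(3.00) # 0.851
#' @export
revised_power <- function(theta_revised, z_crit = NULL) {
  z_crit <- z_crit %||% default_z_crit
  stats::pnorm(theta_revised - z_crit)
}

#' Starting time for inefficacy monitoring
#'
#' The information fraction from which a z-score going in the wrong
#' direction (`Z < 0`) implies that a nominal two-sided 95% confidence
#' interval excludes the effect the trial was powered for:
#' `t0 = (qnorm(0.975) / (z_alpha + z_beta))^2`.
#'
#' @param alpha One-sided type I error rate.
#' @param beta Type II error rate (`1 - power`).
#' @param nominal_level Two-sided level of the nominal confidence interval
#'   defining "wrong direction"; default 0.05.
#' @return The information fraction `t0` in (0, 1).
#' @examples
#' freidlin_t0(0.025, 0.10)
#' @export
freidlin_t0 <- function(alpha = 0.025, beta, nominal_level = 0.05) {
  check_prob(alpha, "alpha")
  check_prob(beta, "beta")
  check_prob(nominal_level, "nominal_level")
  (stats::qnorm(1 - nominal_level / 2) /
     (stats::qnorm(1 - alpha) + stats::qnorm(1 - beta)))^2
}

#' Inefficacy monitoring check
#'
#' Evaluates one interim look against an inefficacy-monitoring strategy.
#' Monitoring starts at `t0` (see [freidlin_t0()]); earlier looks always
#' continue.
#'
#' * Strategy 1: stop whenever `t >= t0` and `z < 0`.
#' * Strategy 2: at the first monitored look stop if `z < 0`; later, stop
#'   when the nominal two-sided 95% confidence interval for the drift,
#'   `z / sqrt(t) +/- qnorm(0.975) / sqrt(t)`, lies entirely below the design
#'   drift `theta` (equivalently, when
#'   `(z + qnorm(0.975)) / sqrt(t) < theta` — at `t = t0` this coincides with
#'   `z < 0`).
#' * Strategy 3: as strategy 2, but the drift that must be excluded shrinks
#'   linearly from `theta` at `t0` to 0 at `t = 1`, making late stopping
#'   progressively harder; this is one concrete reading of a sliding-scale
#'   rule and is recorded in the output.
#'
#' The single-look rule that stops at half information when more events have
#' occurred on treatment than control (`z < 0` at `t = 0.5`) is strategy 1
#' with `t0 = 0.5` and one interim look.
#'
#' @param t Information fraction of the look.
#' @param z Interim z-score (positive favors treatment).
#' @param theta Drift the trial was powered for.
#' @param strategy 1, 2 or 3.
#' @param t0 Monitoring start time; defaults to [freidlin_t0()] at `alpha`
#'   and `beta`.
#' @param alpha,beta Used only to default `t0`.
#' @param nominal_level Two-sided level of the nominal interval.
#' @return A one-row tibble: `t`, `z`, `strategy`, `t0`, `theta_excluded`
#'   (the drift the interval must exclude; `NA` for strategy 1), `stop`, and
#'   a human-readable `rationale`.
#' @examples
#' inefficacy_check(t = 0.5, z = -0.1, theta = drift_from_power(0.9),
#'                  strategy = 1)
#' @export
inefficacy_check <- function(t, z, theta, strategy = 1, t0 = NULL,
                             alpha = 0.025, beta = 1 - power_from_drift(theta),
                             nominal_level = 0.05) {
  check_fraction(t)
  if (!strategy %in% 1:3) abort_domain("`strategy` must be 1, 2 or 3.")
  t0 <- t0 %||% freidlin_t0(alpha, beta, nominal_level)
  zq <- stats::qnorm(1 - nominal_level / 2)
  theta_excl <- NA_real_
  if (t < t0) {
    stop_now <- FALSE
    why <- sprintf("monitoring starts at t0 = %.3f; continue", t0)
  } else if (strategy == 1) {
    stop_now <- z < 0
    why <- if (stop_now) "z < 0 after t0: stop" else "z >= 0: continue"
  } else {
    w <- if (strategy == 3) max(0, (1 - t) / (1 - t0)) else 1
    theta_excl <- theta * w
    upper_ci <- (z + zq) / sqrt(t)
    stop_now <- upper_ci < theta_excl
    why <- sprintf(
      "drift CI upper limit %.3f %s exclusion target %.3f: %s",
      upper_ci, if (stop_now) "below" else "not below", theta_excl,
      if (stop_now) "stop" else "continue"
    )
  }
  tibble::tibble(t = t, z = z, strategy = as.integer(strategy), t0 = t0,
                 theta_excluded = theta_excl, stop = stop_now,
                 rationale = why)
}
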