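#' Interim state of a two-arm binary-endpoint trial
#'
#' Snapshot of a trial comparing event proportions between an intervention
#' and a control arm: per-arm target sizes, observed sizes and event counts,
#' and the event probabilities assumed for the not-yet-observed participants.
#'
#' @param N_c,N_i Target per-arm sample sizes (control, intervention).
#' @param n_c,n_i Observed per-arm sample sizes.
#' @param x_c,x_i Observed per-arm event counts.
#' @param pi_c,pi_i Assumed event probabilities for future participants; for
#'   the observed-trend assumption use `x/n`.
#' @return An object of class `binary_trial_state`.
#' @examples
#' binary_trial_state(N_c = 1212, N_i = 1212, n_c = 606, n_i = 606,
#'                    x_c = 123, x_i = 90, pi_c = 0.2, pi_i = 0.2)
#' @export
binary_trial_state <- function(N_c, N_i, n_c, n_i, x_c, x_i, pi_c, pi_i) {
  vals <- c(N_c = N_c, N_i = N_i, n_c = n_c, n_i = n_i, x_c = x_c, x_i = x_i)
  if (anyNA(vals) || any(vals < 0)) abort_domain("Counts must be non-negative.")
  if (x_c > n_c || x_i > n_i) abort_domain("Event counts cannot exceed arm sizes.")
  if (n_c > N_c || n_i > N_i) abort_domain("Observed sizes cannot exceed targets.")
  check_prob(pi_c, "pi_c", open_lower = FALSE, open_upper = FALSE)
  check_prob(pi_i, "pi_i", open_lower = FALSE, open_upper = FALSE)
  structure(
    list(N_c = N_c, N_i = N_i, n_c = n_c, n_i = n_i, x_c = x_c, x_i = x_i,
         pi_c = pi_c, pi_i = pi_i),
    class = "binary_trial_state"
  )
}

#' @export
print.binary_trial_state <- function(x, ...) {
  cat(sprintf(
    "<binary_trial_state> control %d/%d of %d, intervention %d/%d of %d; future pi = (%.3f, %.3f)\n",
    x$x_c, x$n_c, x$N_c, x$x_i, x$n_i, x$N_i, x$pi_c, x$pi_i
  ))
  invisible(x)
}

#' Predicted end-of-trial intervals for a binary endpoint
#'
#' Simulates the unobserved remainder of each arm as
#' `Binomial(N - n, pi)`, pools observed and simulated events into final
#' proportions `p_c`, `p_i`, and forms the Wald interval
#' `estimate +/- z * sqrt(p_c (1 - p_c) / N_c + p_i (1 - p_i) / N_i)`.
#' The estimate is reported as the intervention-minus-control difference
#' `p_i - p_c`, so a treatment that prevents events gives negative values and
#' the null is 0. When `n = N` in both arms there is nothing to simulate and
#' every draw is the ordinary Wald interval on the observed data.
#'
#' @param state A [binary_trial_state()].
#' @param coverage Interval coverage probability, default 0.95.
#' @param n_draws Number of independent predicted intervals to generate.
#' @param seed Optional integer seed.
#' @return A tibble with columns `replicate`, `estimate`, `lower`, `upper`.
#' @examples
#' st <- binary_trial_state(1212, 1212, 606, 606, 123, 90, 0.2, 0.2)
#' binary_predicted_interval(st, n_draws = 3, seed = 1)
#' @export
binary_predicted_interval <- function(state, coverage = 0.95, n_draws = 1,
                                      seed = NULL) {
  stopifnot(inherits(state, "binary_trial_state"))
  check_prob(coverage, "coverage")
  zq <- stats::qnorm(1 - (1 - coverage) / 2)
  with_seed_maybe(seed, {
    fut_c <- stats::rbinom(n_draws, state$N_c - state$n_c, state$pi_c)
    fut_i <- stats::rbinom(n_draws, state$N_i - state$n_i, state$pi_i)
    p_c <- (state$x_c + fut_c) / state$N_c
    p_i <- (state$x_i + fut_i) / state$N_i
    est <- p_i - p_c
    se <- sqrt(p_c * (1 - p_c) / state$N_c + p_i * (1 - p_i) / state$N_i)
    tibble::tibble(
      replicate = seq_len(n_draws),
      estimate = est, lower = est - zq * se, upper = est + zq * se
    )
  })
}

#' Observed-data Wald interval at an interim analysis
#'
#' @inheritParams binary_predicted_interval
#' @return A one-row tibble with `estimate`, `lower`, `upper`, `width`.
#' @export
binary_observed_interval <- function(state, coverage = 0.95) {
  stopifnot(inherits(state, "binary_trial_state"))
  zq <- stats::qnorm(1 - (1 - coverage) / 2)
  p_c <- state$x_c / state$n_c
  p_i <- state$x_i / state$n_i
  est <- p_i - p_c
  se <- sqrt(p_c * (1 - p_c) / state$n_c + p_i * (1 - p_i) / state$n_i)
  tibble::tibble(estimate = est, lower = est - zq * se, upper = est + zq * se,
                 width = 2 * zq * se)
}

#' Interim state of a survival-endpoint trial on the B-value scale
#'
#' Summary of a time-to-event trial at an interim analysis: observed and
#' targeted event counts (`t = d / D`), the logrank z-score (positive values
#' favor treatment), and the allocation ratio linking the drift to the log
#' hazard ratio: `theta = -log(HR) * sqrt(D / 4)` for 1:1 randomization and
#' `-log(HR) * sqrt(2 * D / 9)` for 2:1, so a benefit (HR < 1) maps to a
#' positive drift.
#'
#' @param d,D Observed and targeted numbers of events, `0 < d <= D`.
#' @param z Interim logrank z-score.
#' @param allocation `"1:1"` or `"2:1"` randomization.
#' @return An object of class `survival_interim_state`.
#' @export
survival_interim_state <- function(d, D, z, allocation = c("1:1", "2:1")) {
  allocation <- match.arg(allocation)
  if (!is.numeric(d) || !is.numeric(D) || d <= 0 || d > D) {
    abort_domain("Event counts must satisfy 0 < d <= D.")
  }
  structure(
    list(d = d, D = D, t = d / D, z = z, b = sqrt(d / D) * z,
         allocation = allocation),
    class = "survival_interim_state"
  )
}

hr_drift_const <- function(state) {
  if (state$allocation == "1:1") sqrt(state$D / 4) else sqrt(2 * state$D / 9)
}

#' Drift assumed for future survival data
#'
#' Either the current trend `theta = b / t` or the drift implied by a
#' hypothesized hazard ratio at the target event count.
#'
#' @param state A [survival_interim_state()].
#' @param hr Hypothesized hazard ratio; omit to use the observed trend.
#' @return A single drift value.
#' @export
survival_drift <- function(state, hr = NULL) {
  stopifnot(inherits(state, "survival_interim_state"))
  if (is.null(hr)) {
    state$b / state$t
  } else {
    if (hr <= 0) abort_domain("`hr` must be positive.")
    -log(hr) * hr_drift_const(state)
  }
}

#' Predicted final z-scores and hazard-ratio intervals
#'
#' Avoids modelling individual event times by simulating the final statistic
#' directly: `Z(1) = b + theta * (1 - t) + N(0, sqrt(1 - t))`, with interval
#' limits `Z(1) +/- z_coverage`. Limits are back-transformed to the
#' hazard-ratio scale by inverting the allocation-specific drift relation at
#' the target event count. At `t = 1` there is no future information and the
#' observed final value is returned without noise.
#'
#' @inheritParams binary_predicted_interval
#' @param state A [survival_interim_state()].
#' @param hr Hypothesized hazard ratio for the future drift; omit for the
#'   observed trend.
#' @return A tibble with columns `replicate`, `z_final`, `z_lower`,
#'   `z_upper`, `estimate` (predicted HR), `lower`, `upper` (HR interval).
#' @export
survival_predicted_interval <- function(state, hr = NULL, coverage = 0.95,
                                        n_draws = 1, seed = NULL) {
  stopifnot(inherits(state, "survival_interim_state"))
  check_prob(coverage, "coverage")
  theta <- survival_drift(state, hr)
  zq <- stats::qnorm(1 - (1 - coverage) / 2)
  cc <- hr_drift_const(state)
  t <- state$t
  with_seed_maybe(seed, {
    noise <- if (t >= 1) rep(0, n_draws) else stats::rnorm(n_draws, 0, sqrt(1 - t))
    z1 <- state$b + theta * (1 - t) + noise
    z_lo <- z1 - zq
    z_hi <- z1 + zq
    tibble::tibble(
      replicate = seq_len(n_draws),
      z_final = z1, z_lower = z_lo, z_upper = z_hi,
      estimate = exp(-z1 / cc),
      lower = exp(-z_hi / cc), # HR transform is decreasing in z
      upper = exp(-z_lo / cc)
    )
  })
}

#' Predicted-interval plots (PIP)
#'
#' Generates `M` replicate predicted end-of-trial intervals under a stated
#' assumption about the unobserved data, groups the replicates by how central
#' their point estimates are, and summarizes with the replicate at the median
#' (percentile grouping) or at the mode of a kernel-density estimate of the
#' point-estimate distribution (`"cpdf_mode"` grouping). Plotted with
#' [autoplot()], brighter lines mark more central replicates and a vertical
#' line marks the null value.
#'
#' Percentile grouping uses four brightness bands at the 50/80/95/100 central
#' percentile shells of the estimate distribution; `"cpdf_mode"` bands by the
#' same quantile shells of kernel-density height (Gaussian kernel,
#' normal-reference bandwidth).
#'
#' @param state A [binary_trial_state()] or [survival_interim_state()].
#' @param M Number of replicates (at least 2); 500 is typical for plots,
#'   10000 for stable medians.
#' @param coverage Interval coverage probability.
#' @param grouping `"percentile"` or `"cpdf_mode"`.
#' @param seed Optional integer seed, recorded in the result.
#' @param ... Passed to the endpoint-specific interval generator (e.g. `hr`
#'   for survival states).
#' @return An object of class `pip`: [tidy()] gives the per-replicate tibble
#'   (`replicate`, `estimate`, `lower`, `upper`, `group`), [glance()] the
#'   summary row and interval widths, [autoplot()] the plot.
#' @examples
#' st <- binary_trial_state(1212, 1212, 606, 606, 123, 90, 0.2, 0.15)
#' p <- pip(st, M = 200, seed = 42)
#' glance(p)
#' @export
pip <- function(state, M = 500, coverage = 0.95,
                grouping = c("percentile", "cpdf_mode"), seed = NULL, ...) {
  UseMethod("pip")
}

#' @export
pip.binary_trial_state <- function(state, M = 500, coverage = 0.95,
                                   grouping = c("percentile", "cpdf_mode"),
                                   seed = NULL, ...) {
  draws <- binary_predicted_interval(state, coverage, n_draws = check_M(M),
                                     seed = seed)
  new_pip(draws, match.arg(grouping), state, coverage, seed, null_value = 0)
}

#' @export
pip.survival_interim_state <- function(state, M = 500, coverage = 0.95,
                                       grouping = c("percentile", "cpdf_mode"),
                                       seed = NULL, hr = NULL, ...) {
  draws <- survival_predicted_interval(state, hr = hr, coverage = coverage,
                                       n_draws = check_M(M), seed = seed)
  new_pip(draws[c("replicate", "estimate", "lower", "upper")],
          match.arg(grouping), state, coverage, seed, null_value = 1)
}

check_M <- function(M) {
  if (!is.numeric(M) || length(M) != 1 || M < 2) {
    abort_domain("`M` must be at least 2.")
  }
  as.integer(M)
}

new_pip <- function(draws, grouping, state, coverage, seed, null_value) {
  est <- draws$estimate
  M <- length(est)
  if (stats::sd(est) < 1e-14) {
    # degenerate (fully observed) state: all replicates identical
    group <- rep(1L, M)
    central <- 1L
  } else if (grouping == "percentile") {
    centrality <- 2 * abs(rank(est, ties.method = "average") / M - 0.5)
    group <- cut(centrality, c(-Inf, 0.5, 0.8, 0.95, Inf), labels = FALSE)
    central <- which.min(abs(est - stats::median(est)))
  } else {
    dens <- stats::density(est, bw = stats::bw.nrd(est))
    h <- stats::approx(dens$x, dens$y, xout = est, rule = 2)$y
    shell <- 1 - rank(h, ties.method = "average") / M # 0 at the mode
    group <- cut(shell, c(-Inf, 0.5, 0.8, 0.95, Inf), labels = FALSE)
    central <- which.max(h)
  }
  draws$group <- group
  structure(
    list(
      draws = draws,
      summary = draws[central, c("estimate", "lower", "upper")],
      grouping = grouping, coverage = coverage, seed = seed,
      null_value = null_value, state = state, M = M
    ),
    class = "pip"
  )
}

#' @export
print.pip <- function(x, ...) {
  cat(sprintf("<pip> %d replicates (%s grouping), %.0f%% intervals\n",
              x$M, x$grouping, 100 * x$coverage))
  cat("summary replicate:\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.pip <- function(x, ...) x$draws

#' @export
glance.pip <- function(x, ...) {
  tibble::tibble(
    M = x$M, grouping = x$grouping, coverage = x$coverage,
    estimate = x$summary$estimate,
    lower = x$summary$lower, upper = x$summary$upper,
    width = x$summary$upper - x$summary$lower,
    median_estimate = stats::median(x$draws$estimate)
  )
}

#' @rdname pip
#' @param object A `pip` object.
#' @export
autoplot.pip <- function(object, ...) {
  df <- object$draws
  df <- df[order(df$estimate), ]
  df$y <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lower, xend = .data$upper,
                                       yend = .data$y,
                                       alpha = -.data$group)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$estimate), size = 0.4) +
    ggplot2::geom_vline(xintercept = object$null_value, linetype = 2) +
    ggplot2::scale_alpha_continuous(range = c(0.15, 1), guide = "none") +
    ggplot2::labs(
      x = "predicted end-of-trial estimate and interval",
      y = "replicate (sorted)",
      title = sprintf("Predicted interval plot (M = %d)", object$M)
    )
}

#' Fractional reduction in interval width
#'
#' `1 - predicted_width / observed_width`: the efficiency gain, in interval
#' width, from completing the trial rather than stopping at the interim.
#'
#' @param observed Observed-interval width, or a length-2 `c(lower, upper)`.
#' @param predicted Predicted-interval width, or a length-2 `c(lower, upper)`.
#' @return The fractional width reduction.
#' @examples
#' interval_width_reduction(0.085, 0.062)
#' @export
interval_width_reduction <- function(observed, predicted) {
  w <- function(x) if (length(x) == 2) diff(x) else x
  ow <- w(observed)
  pw <- w(predicted)
  if (!is.numeric(ow) || !is.numeric(pw) || ow <= 0 || pw <= 0) {
    abort_domain("Widths must be positive (or supply c(lower, upper)).")
  }
  1 - pw / ow
}
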