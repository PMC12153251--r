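#' Interim monitoring states
#'
#' Builds a tibble of interim-analysis snapshots on the Brownian-motion scale
#' used throughout the package. Each row is one look, described by the
#' information fraction `t`, the interim z-score `z`, and the B-value
#' `b = sqrt(t) * z`. Either `z` or `b` may be supplied; the other is derived.
#'
#' The information fraction is the ratio of the statistical information
#' accrued so far to the information at the planned end of the trial; for
#' non-survival endpoints it is well approximated by the sample-size ratio and
#' for survival endpoints by the event-count ratio. The B-value is the
#' canonical scale on which the sequence of test statistics behaves like a
#' Brownian motion with drift: increments over information time are
#' independent normals.
#'
#' @param t Information fraction(s), in (0, 1].
#' @param z Interim z-score(s), parameterized so that positive values favor
#'   the investigational treatment. Exactly one of `z`, `b` is required.
#' @param b Interim B-value(s), `b = sqrt(t) * z`.
#' @return A tibble with columns `t`, `z`, `b`, one row per look.
#' @examples
#' interim_state(t = 0.5, z = 0.3)
#' interim_state(t = c(0.25, 0.5), b = c(0.1, 0.212))
#' @export
interim_state <- function(t, z = NULL, b = NULL) {
  check_fraction(t)
  if (is.null(z) && is.null(b)) {
    abort_domain("Supply one of `z` or `b`.")
  }
  if (!is.null(z) && !is.null(b)) {
    if (any(abs(b - sqrt(t) * z) > 1e-12)) {
      abort_domain("`b` must equal sqrt(t) * z when both are given.")
    }
  }
  if (is.null(z)) z <- b / sqrt(t)
  if (is.null(b)) b <- sqrt(t) * z
  tibble::tibble(t = as.numeric(t), z = as.numeric(z), b = as.numeric(b))
}

as_interim_state <- function(data) {
  if (!is.data.frame(data) || !("t" %in% names(data))) {
    abort_domain("`data` must be a data frame with a `t` column (see interim_state()).")
  }
  z <- if ("z" %in% names(data)) data$z else NULL
  b <- if ("b" %in% names(data)) data$b else NULL
  st <- interim_state(data$t, z = z, b = b)
  extra <- setdiff(names(data), names(st))
  dplyr::bind_cols(st, data[extra])
}

#' Information fraction
#'
#' Ratio of interim to final statistical information, `t = I / I_end`. Counts
#' (events for survival endpoints, per-arm sample sizes otherwise) are the
#' usual stand-ins for information.
#'
#' @param current_info Information (or count) accrued at the interim look.
#' @param final_info Information (or count) at the planned end of the trial.
#' @return The information fraction(s) in (0, 1].
#' @examples
#' information_fraction(346, 713)
#' @export
information_fraction <- function(current_info, final_info) {
  if (!is.numeric(current_info) || !is.numeric(final_info) ||
      anyNA(current_info) || anyNA(final_info)) {
    abort_domain("Information values must be numeric and non-missing.")
  }
  if (any(current_info <= 0) || any(final_info <= 0)) {
    abort_domain("Information values must be positive.")
  }
  if (any(current_info > final_info)) {
    abort_domain("`current_info` cannot exceed `final_info`.")
  }
  current_info / final_info
}

#' B-value from an interim z-score
#'
#' `B(t) = sqrt(t) * Z(t)`; at `t = 1` the B-value and the z-score coincide.
#'
#' @inheritParams interim_state
#' @return The B-value(s).
#' @examples
#' b_value(0.5, 0.3)
#' @export
b_value <- function(t, z) {
  check_fraction(t)
  sqrt(t) * z
}

#' Drift parameter implied by design power
#'
#' The drift parameter is the expected final z-score, `theta = E[Z(1)]`. A
#' design with one-sided level `alpha` and power `1 - beta` corresponds to
#' `theta = z_crit + qnorm(power)`: for example 2.80, 3.00 and 3.24 for 80%,
#' 85% and 90% power at `z_crit = 1.96`.
#'
#' @param power Intended unconditional power, in (0, 1).
#' @param alpha One-sided type I error rate, in (0, 0.5). Only used to default
#'   `z_crit` when that is not given.
#' @param z_crit Critical value for the final test; defaults to 1.96.
#' @return The drift parameter(s).
#' @seealso [power_from_drift()] for the inverse map.
#' @examples
#' drift_from_power(0.90) # 3.2416
#' @export
drift_from_power <- function(power, alpha = 0.025, z_crit = NULL) {
  check_prob(power, "power")
  check_prob(alpha, "alpha")
  if (any(alpha >= 0.5)) abort_domain("`alpha` must be below 0.5 (one-sided).")
  z_crit <- z_crit %||% default_z_crit
  z_crit + stats::qnorm(power)
}

#' Unconditional power implied by a drift parameter
#'
#' `power = pnorm(theta - z_crit)`; inverse of [drift_from_power()].
#'
#' @param theta Drift parameter (expected final z-score).
#' @inheritParams drift_from_power
#' @return Power value(s) in (0, 1).
#' @export
power_from_drift <- function(theta, z_crit = NULL) {
  z_crit <- z_crit %||% default_z_crit
  stats::pnorm(theta - z_crit)
}

#' Conditional power
#'
#' Probability of a statistically significant final result given the interim
#' data and an assumed drift `theta`:
#' `CP = pnorm((b + theta * (1 - t) - z_crit) / sqrt(1 - t))`.
#' The drift is usually either the originally hypothesized effect
#' ([drift_from_power()]) or the current trend ([current_trend_drift()]); the
#' former is the stable choice for futility guidelines, the latter is highly
#' variable early in a trial.
#'
#' @param data A data frame of interim looks with columns `t` and `z` (or
#'   `b`), e.g. from [interim_state()]. Interim looks require `t < 1`; at the
#'   end of the trial compare `z` to `z_crit` directly.
#' @param theta Assumed drift parameter, recycled across rows.
#' @param z_crit Critical value for the final test; defaults to 1.96.
#' @return `data` with an added numeric column `cp`.
#' @examples
#' interim_state(0.5, z = 0.3) |> conditional_power(theta = drift_from_power(0.85))
#' @export
conditional_power <- function(data, theta, z_crit = NULL) {
  st <- as_interim_state(data)
  check_fraction(st$t, allow_one = FALSE)
  z_crit <- z_crit %||% default_z_crit
  arg <- (st$b + theta * (1 - st$t) - z_crit) / sqrt(1 - st$t)
  dplyr::mutate(st, cp = stats::pnorm(arg))
}

#' Current-trend drift estimate
#'
#' The drift implied by the interim data alone, `theta_hat = B(t) / t`
#' (equivalently `z / sqrt(t)`): the slope of the line from the origin through
#' the observed B-value.
#'
#' @inheritParams conditional_power
#' @return `data` with an added column `theta_trend`.
#' @examples
#' interim_state(0.5, b = 0.212) |> current_trend_drift()
#' @export
current_trend_drift <- function(data) {
  st <- as_interim_state(data)
  dplyr::mutate(st, theta_trend = .data$b / .data$t)
}

#' Reverse conditional power
#'
#' Probability, given a barely significant final result `Z(1) = z_crit`, of
#' interim results at least as disappointing as those observed:
#' `RCP = pnorm((z * sqrt(t) - z_crit * t) / sqrt(t * (1 - t)))`.
#' Unlike conditional power, RCP requires no assumption about the treatment
#' effect: conditioning on the final z-score removes the drift. A common
#' reverse stochastic-curtailment guideline stops for futility when
#' `RCP <= 0.025`.
#'
#' @inheritParams conditional_power
#' @return `data` with an added numeric column `rcp`.
#' @examples
#' interim_state(0.485, z = 0.733) |> reverse_conditional_power()
#' @export
reverse_conditional_power <- function(data, z_crit = NULL) {
  st <- as_interim_state(data)
  check_fraction(st$t, allow_one = FALSE)
  z_crit <- z_crit %||% default_z_crit
  arg <- (st$z * sqrt(st$t) - z_crit * st$t) / sqrt(st$t * (1 - st$t))
  dplyr::mutate(st, rcp = stats::pnorm(arg))
}

#' Predictive probability of success
#'
#' Conditional power averaged over the posterior distribution of the drift
#' under a normal prior `theta ~ N(theta0, sigma0_sq)`:
#' \deqn{PPoS(t) = \Phi\left(\frac{(b - z_c)(1 + t\sigma_0^2) +
#'   (1 - t)(\theta_0 + b\sigma_0^2)}
#'   {\sqrt{(1 - t)(1 + \sigma_0^2)(1 + t\sigma_0^2)}}\right)}
#' With `sigma0_sq = 0` the prior is a point mass and PPoS reduces exactly to
#' conditional power at `theta = theta0`; with a diffuse prior it shrinks
#' toward the current trend. PPoS is a compromise between conditional power
#' under the hypothesized and the observed effects.
#'
#' @inheritParams conditional_power
#' @param theta0 Prior mean of the drift parameter.
#' @param sigma0_sq Prior variance of the drift parameter, `>= 0`.
#' @return `data` with an added numeric column `ppos`.
#' @examples
#' interim_state(0.5, z = 0.3) |> ppos(theta0 = 3, sigma0_sq = 1)
#' @export
ppos <- function(data, theta0, sigma0_sq, z_crit = NULL) {
  st <- as_interim_state(data)
  check_fraction(st$t, allow_one = FALSE)
  if (!is.numeric(sigma0_sq) || any(sigma0_sq < 0)) {
    abort_domain("`sigma0_sq` must be a non-negative prior variance.")
  }
  z_crit <- z_crit %||% default_z_crit
  t <- st$t
  b <- st$b
  num <- (b - z_crit) * (1 + t * sigma0_sq) + (1 - t) * (theta0 + b * sigma0_sq)
  den <- sqrt((1 - t) * (1 + sigma0_sq) * (1 + t * sigma0_sq))
  dplyr::mutate(st, ppos = stats::pnorm(num / den))
}

#' Type II error bound under continuous stochastic curtailment
#'
#' If a trial with no-monitoring type II error `beta` is monitored
#' continuously and stopped whenever conditional power under the originally
#' hypothesized effect falls to `gamma_threshold` or below, the type II error
#' rate is at most `beta / (1 - gamma_threshold)`.
#'
#' @param beta Type II error rate with no monitoring, in (0, 1).
#' @param gamma_threshold Curtailment threshold on conditional power, in
#'   `[0, 1)`.
#' @return The bound `beta / (1 - gamma_threshold)`.
#' @examples
#' continuous_curtailment_beta(0.10, 0.20) # 0.125
#' @export
continuous_curtailment_beta <- function(beta, gamma_threshold) {
  check_prob(beta, "beta")
  check_prob(gamma_threshold, "gamma_threshold", open_lower = FALSE)
  beta / (1 - gamma_threshold)
}
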