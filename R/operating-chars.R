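#' Futility rules
#'
#' A futility rule is applied at interim looks only (never at the final
#' analysis) and stops the trial when its statistic falls to the threshold or
#' below:
#' * `"cp_original"` — conditional power under the originally hypothesized
#'   drift drops to `threshold` (commonly Gamma = 0.2) or below;
#' * `"cp_current_trend"` — conditional power under the current-trend drift
#'   `B(t)/t` drops to `threshold` or below;
#' * `"rcp"` — reverse conditional power drops to `threshold` (commonly
#'   0.025) or below;
#' * `"z_threshold"` — the interim z-score itself drops below a fixed value.
#'
#' @param kind Rule family; see Details.
#' @param threshold Probability threshold (CP/RCP rules) or z-value
#'   (`"z_threshold"`).
#' @return An object of class `futility_rule`.
#' @examples
#' futility_rule("cp_current_trend", 0.20)
#' @export
futility_rule <- function(kind = c("cp_original", "cp_current_trend", "rcp",
                                   "z_threshold"),
                          threshold) {
  kind <- match.arg(kind)
  if (kind != "z_threshold") check_prob(threshold, "threshold")
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold)) {
    abort_domain("`threshold` must be a single finite number.")
  }
  structure(list(kind = kind, threshold = threshold), class = "futility_rule")
}

#' @export
print.futility_rule <- function(x, ...) {
  cat(sprintf("<futility_rule> stop when %s <= %g\n",
              switch(x$kind,
                     cp_original = "CP (original hypothesis)",
                     cp_current_trend = "CP (current trend)",
                     rcp = "RCP",
                     z_threshold = "interim z"),
              x$threshold))
  invisible(x)
}

#' Per-look z-score thresholds of a futility rule
#'
#' Inverts the rule's defining statistic at each interim look: the returned
#' value is the largest interim z-score at which the rule still triggers.
#' CP under the current trend equals `pnorm((z / sqrt(t) - z_crit) /
#' sqrt(1 - t))`, so its threshold is
#' `sqrt(t) * (z_crit + qnorm(Gamma) * sqrt(1 - t))`; the CP-under-original
#' and RCP inversions are the analogous closed forms.
#'
#' @param rule A [futility_rule()].
#' @param times Interim information fractions (all `< 1`).
#' @param theta Design drift; required for `kind = "cp_original"`.
#' @param z_crit Critical value for the final test; defaults to 1.96.
#' @return A tibble with columns `look`, `t`, `z_stop`.
#' @examples
#' rule_thresholds(futility_rule("rcp", 0.025), times = 0.5)
#' @export
rule_thresholds <- function(rule, times, theta = NULL, z_crit = NULL) {
  stopifnot(inherits(rule, "futility_rule"))
  check_fraction(times, "times", allow_one = FALSE)
  z_crit <- z_crit %||% default_z_crit
  thr <- rule$threshold
  z_stop <- switch(rule$kind,
    cp_current_trend =
      sqrt(times) * (z_crit + stats::qnorm(thr) * sqrt(1 - times)),
    cp_original = {
      if (is.null(theta)) {
        abort_domain("`theta` is required for a cp_original rule.")
      }
      (z_crit + stats::qnorm(thr) * sqrt(1 - times) - theta * (1 - times)) /
        sqrt(times)
    },
    rcp =
      (z_crit * times + stats::qnorm(thr) * sqrt(times * (1 - times))) /
        sqrt(times),
    z_threshold = rep(thr, length(times))
  )
  tibble::tibble(look = seq_along(times), t = times, z_stop = z_stop)
}

#' Operating characteristics of a futility rule
#'
#' Type II error rate of a pure futility design: the rule is checked at each
#' interim look, there is no interim efficacy stopping, and the final
#' analysis at `t = 1` rejects if and only if `Z(1) >= z_crit`. The rule is
#' converted to per-look z thresholds and evaluated under the design drift by
#' [crossing_probabilities()]; the type II error is the probability of a
#' futility stop at any interim plus the probability of reaching the end and
#' failing the final test.
#'
#' @inheritParams rule_thresholds
#' @param times Full look schedule, ending at 1 (the final analysis);
#'   futility is assessed at the earlier looks.
#' @param power Intended unconditional power; used to derive `theta` when
#'   that is not given.
#' @param theta Drift under which the type II error is computed; defaults to
#'   [drift_from_power()] at `power`.
#' @param upper Optional per-interim efficacy z-boundaries for combined
#'   designs; default none (`Inf`).
#' @return An object of class `futility_oc`: per-look stop probabilities (a
#'   tibble via [tidy()]) and totals via [glance()]; the scalar type II error
#'   is in `$type2_error`.
#' @examples
#' oc <- futility_oc(futility_rule("cp_current_trend", 0.2),
#'                   times = (1:6) / 6, power = 0.90)
#' oc$type2_error
#' @export
futility_oc <- function(rule, times, power = NULL, theta = NULL,
                        z_crit = NULL, upper = NULL) {
  stopifnot(inherits(rule, "futility_rule"))
  validate_schedule(times)
  k <- length(times)
  if (abs(times[k] - 1) > 1e-12) {
    abort_domain("`times` must end with the final analysis at t = 1.")
  }
  z_crit <- z_crit %||% default_z_crit
  if (is.null(theta)) {
    if (is.null(power)) abort_domain("Supply `power` or `theta`.")
    theta <- drift_from_power(power, z_crit = z_crit)
  }
  interim <- times[-k]
  if (length(interim)) {
    thr <- rule_thresholds(rule, interim, theta = theta, z_crit = z_crit)$z_stop
  } else {
    thr <- numeric(0)
  }
  up <- c(upper %||% rep(Inf, k - 1), z_crit)
  lo <- c(thr, z_crit)
  cp <- crossing_probabilities(times, lower = lo, upper = up, theta = theta)
  per_look <- tibble::tibble(
    look = cp$look, t = cp$t, z_stop = lo,
    p_stop = cp$fcp_lower
  )
  structure(
    list(
      rule = rule, times = times, theta = theta, z_crit = z_crit,
      per_look = per_look,
      type2_error = sum(cp$fcp_lower),
      per_look_stop_prob = cp$fcp_lower[-k],
      p_fail_final = cp$fcp_lower[k],
      p_reject = sum(cp$fcp_upper)
    ),
    class = "futility_oc"
  )
}

#' @export
print.futility_oc <- function(x, ...) {
  cat(sprintf("<futility_oc> %d looks, theta = %.4f, type II error = %.4f\n",
              length(x$times), x$theta, x$type2_error))
  print(x$per_look)
  invisible(x)
}

#' @export
tidy.futility_oc <- function(x, ...) x$per_look

#' @export
glance.futility_oc <- function(x, ...) {
  tibble::tibble(
    kind = x$rule$kind, threshold = x$rule$threshold,
    n_looks = length(x$times), theta = x$theta,
    type2_error = x$type2_error, p_fail_final = x$p_fail_final,
    power = 1 - x$type2_error
  )
}

#' Sweep a futility rule over powers and look counts
#'
#' Regenerates the operating-characteristics tables for equally spaced look
#' schedules: `K` total analyses at `t = j/K`, futility assessed at the
#' `K - 1` interims. With `K = 1` there are no interim looks and the type II
#' error equals `1 - power` exactly.
#'
#' @inheritParams futility_oc
#' @param powers Unconditional powers to tabulate.
#' @param n_looks Numbers of equally spaced analyses (including the final).
#' @return A tibble with columns `power`, `n_looks`, `type2_error`.
#' @examples
#' \donttest{
#' oc_table(futility_rule("rcp", 0.025), powers = 0.9, n_looks = 1:6)
#' }
#' @export
oc_table <- function(rule, powers, n_looks, z_crit = NULL) {
  grid <- tidyr::expand_grid(power = powers, n_looks = n_looks)
  grid$type2_error <- mapply(function(p, k) {
    futility_oc(rule, times = seq_len(k) / k, power = p,
                z_crit = z_crit)$type2_error
  }, grid$power, grid$n_looks)
  grid
}
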