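#' Simulate monitored z-score paths
#'
#' Monte-Carlo oracle for the numerical-integration engine: builds B-value
#' paths by summing independent normal increments
#' `B(t2) - B(t1) ~ N(theta * (t2 - t1), t2 - t1)` over the look schedule and
#' converts to z-scores `Z(t) = B(t) / sqrt(t)`. Under this construction
#' `Z(t) ~ N(theta * sqrt(t), 1)` and `cor(Z(t1), Z(t2)) = sqrt(t1 / t2)`.
#'
#' @param times Strictly increasing information fractions in (0, 1].
#' @param theta Drift parameter.
#' @param n_rep Number of replicate paths.
#' @param seed Optional integer seed, recorded in the result.
#' @return An object of class `path_batch`: `z` (an `n_rep x k` matrix of
#'   z-scores), `times`, `theta`, `seed`. [tidy()] returns a long tibble.
#' @examples
#' pb <- simulate_paths(c(0.5, 1), theta = 3, n_rep = 100, seed = 7)
#' colMeans(pb$z)
#' @export
simulate_paths <- function(times, theta, n_rep, seed = NULL) {
  validate_schedule(times)
  if (!is.numeric(n_rep) || n_rep < 1) abort_domain("`n_rep` must be >= 1.")
  n_rep <- as.integer(n_rep)
  k <- length(times)
  dt <- diff(c(0, times))
  b <- with_seed_maybe(seed, {
    inc <- matrix(stats::rnorm(n_rep * k, mean = rep(theta * dt, each = n_rep),
                               sd = rep(sqrt(dt), each = n_rep)),
                  nrow = n_rep, ncol = k)
    for (j in seq_len(k)[-1]) inc[, j] <- inc[, j] + inc[, j - 1]
    inc
  })
  z <- sweep(b, 2, sqrt(times), "/")
  structure(list(z = z, times = times, theta = theta, seed = seed,
                 n_rep = n_rep),
            class = "path_batch")
}

#' @export
print.path_batch <- function(x, ...) {
  cat(sprintf("<path_batch> %d paths x %d looks, theta = %g, seed = %s\n",
              x$n_rep, length(x$times), x$theta,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' @export
tidy.path_batch <- function(x, ...) {
  tibble::tibble(
    replicate = rep(seq_len(x$n_rep), times = length(x$times)),
    look = rep(seq_along(x$times), each = x$n_rep),
    t = rep(x$times, each = x$n_rep),
    z = as.vector(x$z)
  )
}

#' Empirical operating characteristics of boundaries on simulated paths
#'
#' Per-path first-crossing bookkeeping for explicit z-score boundaries:
#' a path stops at its first look with `z <= lower` (futility) or
#' `z >= upper` (efficacy), whichever side is hit. Returns empirical
#' per-look crossing probabilities with binomial standard errors — the
#' Monte-Carlo twin of [crossing_probabilities()].
#'
#' @param batch A [simulate_paths()] result.
#' @param lower,upper Per-look z boundaries (`-Inf` / `Inf` for none). A
#'   final look with `lower == upper` classifies every remaining path.
#' @return A tibble of class `empirical_oc` with per-look `p_lower`,
#'   `p_upper` and standard errors; totals via [glance()]. Attributes carry
#'   `p_continue` and `n_rep`.
#' @export
empirical_oc <- function(batch, lower, upper) {
  stopifnot(inherits(batch, "path_batch"))
  k <- length(batch$times)
  if (length(lower) != k || length(upper) != k) {
    abort_domain("`lower` and `upper` must match the batch schedule.")
  }
  n <- batch$n_rep
  active <- rep(TRUE, n)
  p_lo <- p_up <- numeric(k)
  for (j in seq_len(k)) {
    zj <- batch$z[, j]
    hit_lo <- active & zj < lower[j]
    hit_up <- active & !hit_lo & zj > upper[j]
    if (lower[j] == upper[j]) hit_up <- active & !hit_lo # split all remaining
    p_lo[j] <- sum(hit_lo) / n
    p_up[j] <- sum(hit_up) / n
    active <- active & !hit_lo & !hit_up
  }
  out <- tibble::tibble(
    look = seq_len(k), t = batch$times, lower = lower, upper = upper,
    p_lower = p_lo, se_lower = sqrt(p_lo * (1 - p_lo) / n),
    p_upper = p_up, se_upper = sqrt(p_up * (1 - p_up) / n)
  )
  structure(out, class = c("empirical_oc", class(out)),
            p_continue = sum(active) / n, n_rep = n)
}

#' @export
glance.empirical_oc <- function(x, ...) {
  n <- attr(x, "n_rep")
  p_lo <- sum(x$p_lower)
  p_up <- sum(x$p_upper)
  tibble::tibble(
    n_rep = n,
    p_lower = p_lo, se_lower = sqrt(p_lo * (1 - p_lo) / n),
    p_upper = p_up, se_upper = sqrt(p_up * (1 - p_up) / n),
    p_continue = attr(x, "p_continue")
  )
}

#' Apply a futility rule to simulated paths
#'
#' Converts the rule to per-look z thresholds (final test at `z_crit`) and
#' runs the first-crossing bookkeeping of [empirical_oc()] — the Monte-Carlo
#' twin of [futility_oc()]. The batch schedule must end at `t = 1`.
#'
#' @inheritParams empirical_oc
#' @param rule A [futility_rule()], or `NULL` for no futility stopping (the
#'   empirical type II error is then just the fraction failing the final
#'   test).
#' @param theta Drift for cp_original thresholds; defaults to the batch
#'   drift.
#' @param z_crit Final-test critical value; defaults to 1.96.
#' @return The [empirical_oc()] tibble; the empirical type II error is
#'   `sum(p_lower)`.
#' @export
apply_rule_to_paths <- function(batch, rule = NULL, theta = NULL,
                                z_crit = NULL) {
  stopifnot(inherits(batch, "path_batch"))
  z_crit <- z_crit %||% default_z_crit
  k <- length(batch$times)
  if (abs(batch$times[k] - 1) > 1e-12) {
    abort_domain("the batch schedule must end at t = 1 to apply a final test.")
  }
  theta <- theta %||% batch$theta
  if (is.null(rule)) {
    thr <- rep(-Inf, k - 1)
  } else {
    thr <- rule_thresholds(rule, batch$times[-k], theta = theta,
                           z_crit = z_crit)$z_stop
  }
  empirical_oc(batch,
               lower = c(thr, z_crit),
               upper = c(rep(Inf, k - 1), z_crit))
}

#' Simulate a binary-endpoint trial interim state
#'
#' Fixture generator for the predicted-interval machinery: draws interim
#' per-arm event counts `Binomial(round(interim_fraction * N), pi)` and
#' returns a [binary_trial_state()] whose assumed future probabilities are
#' the generating ones.
#'
#' @param pi_c,pi_i True event probabilities per arm.
#' @param N_c,N_i Target per-arm sample sizes.
#' @param interim_fraction Fraction of each arm observed at the interim, in
#'   (0, 1].
#' @param seed Optional integer seed.
#' @return A [binary_trial_state()].
#' @examples
#' simulate_binary_trial(0.2, 0.15, 1212, 1212, 0.5, seed = 1)
#' @export
simulate_binary_trial <- function(pi_c, pi_i, N_c, N_i, interim_fraction,
                                  seed = NULL) {
  check_prob(pi_c, "pi_c", open_lower = FALSE, open_upper = FALSE)
  check_prob(pi_i, "pi_i", open_lower = FALSE, open_upper = FALSE)
  if (N_c < 1 || N_i < 1) abort_domain("Target sizes must be >= 1.")
  check_fraction(interim_fraction, "interim_fraction")
  n_c <- round(interim_fraction * N_c)
  n_i <- round(interim_fraction * N_i)
  with_seed_maybe(seed, {
    binary_trial_state(
      N_c = N_c, N_i = N_i, n_c = n_c, n_i = n_i,
      x_c = stats::rbinom(1, n_c, pi_c), x_i = stats::rbinom(1, n_i, pi_i),
      pi_c = pi_c, pi_i = pi_i
    )
  })
}
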