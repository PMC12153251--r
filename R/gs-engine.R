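# Recursive numerical integration for discretely observed Brownian motion
# with drift, on the z-score scale.
#
# The "state" carried between looks is the sub-density of paths that have not
# yet crossed a boundary, tabulated on Gauss-Legendre nodes over the
# continuation region. Transitions use the B-value increment law:
# B(t2) - B(t1) ~ N(theta * (t2 - t1), t2 - t1), independent of the past, so
# given Z(t1) = x, Z(t2) ~ N((x*sqrt(t1) + theta*dt)/sqrt(t2), dt/t2).

GS_NODES <- 301L # nodes per look interval; ~1e-10 recursion accuracy
GS_TRUNC <- 8    # truncate integration at marginal mean +/- 8 (z-scale sd 1)

gs_mass <- function(state) if (is.null(state)) 1 else sum(state$w * state$g)

# P(stopped paths survive to `t2` and Z(t2) < l)
gs_lower_prob <- function(state, t2, l, theta) {
  if (l == -Inf) return(0)
  if (l == Inf) return(gs_mass(state))
  if (is.null(state)) {
    return(stats::pnorm(l, mean = theta * sqrt(t2), sd = 1))
  }
  dt <- t2 - state$t
  s <- sqrt(dt)
  sum(state$w * state$g *
        stats::pnorm((l * sqrt(t2) - state$x * sqrt(state$t) - theta * dt) / s))
}

# P(survive to `t2` and Z(t2) > u)
gs_upper_prob <- function(state, t2, u, theta) {
  if (u == Inf) return(0)
  if (u == -Inf) return(gs_mass(state))
  if (is.null(state)) {
    return(stats::pnorm(u, mean = theta * sqrt(t2), sd = 1, lower.tail = FALSE))
  }
  dt <- t2 - state$t
  s <- sqrt(dt)
  sum(state$w * state$g *
        stats::pnorm((u * sqrt(t2) - state$x * sqrt(state$t) - theta * dt) / s,
                     lower.tail = FALSE))
}

# propagate the sub-density through the look at `t2` with continuation
# region [lower, upper]
gs_advance <- function(state, t2, lower, upper, theta, nodes = GS_NODES) {
  mu <- theta * sqrt(t2)
  a <- max(lower, mu - GS_TRUNC)
  b <- min(upper, mu + GS_TRUNC)
  if (!is.finite(a)) a <- mu - GS_TRUNC
  if (!is.finite(b)) b <- mu + GS_TRUNC
  if (b <= a) {
    return(list(t = t2, x = numeric(0), w = numeric(0), g = numeric(0)))
  }
  gl <- pracma::gaussLegendre(nodes, a, b)
  if (is.null(state)) {
    g <- stats::dnorm(gl$x, mean = mu, sd = 1)
  } else if (length(state$x) == 0) {
    g <- numeric(nodes)
  } else {
    dt <- t2 - state$t
    s <- sqrt(dt)
    kern <- stats::dnorm(
      outer(gl$x * sqrt(t2), state$x * sqrt(state$t) + theta * dt, `-`) / s
    )
    g <- as.vector(kern %*% (state$w * state$g)) * sqrt(t2) / s
  }
  list(t = t2, x = gl$x, w = gl$w, g = g)
}

validate_schedule <- function(times) {
  if (length(times) == 0 || !is.numeric(times) || anyNA(times)) {
    abort_domain("`times` must be a non-empty numeric look schedule.")
  }
  if (any(times <= 0) || any(times > 1) || any(diff(times) <= 0)) {
    abort_domain("`times` must be strictly increasing information fractions in (0, 1].")
  }
  invisible(times)
}

#' First-crossing probabilities over a boundary set
#'
#' Computes, by recursive Gauss-Legendre integration of the Brownian-motion
#' increment law, the probability of crossing the lower (futility) boundary
#' for the first time at each look without having first crossed the upper
#' (efficacy) boundary, and vice versa, under drift `theta`.
#'
#' @param times Strictly increasing information fractions in (0, 1].
#' @param lower,upper Per-look z-score boundaries; use `-Inf` / `Inf` for
#'   looks with no boundary on that side. A look with `lower == upper`
#'   (typically the final analysis) splits all remaining probability between
#'   the two crossings.
#' @param theta Drift parameter (expected final z-score).
#' @param nodes Gauss-Legendre nodes per look interval.
#' @return A tibble of class `crossing_probs` with columns `look`, `t`,
#'   `lower`, `upper`, `fcp_lower`, `fcp_upper`, and attributes `p_continue`
#'   (probability of never crossing) and `theta`.
#' @examples
#' crossing_probabilities(c(0.5, 1), lower = c(0, 1.96), upper = c(Inf, 1.96),
#'                        theta = 3)
#' @export
crossing_probabilities <- function(times, lower, upper, theta,
                                   nodes = GS_NODES) {
  validate_schedule(times)
  k <- length(times)
  if (length(lower) != k || length(upper) != k) {
    abort_domain("`lower` and `upper` must have one entry per look.")
  }
  if (any(lower > upper)) abort_domain("`lower` must not exceed `upper`.")
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta)) {
    abort_domain("`theta` must be a single finite drift value.")
  }
  fcp_lo <- fcp_up <- numeric(k)
  state <- NULL
  for (j in seq_len(k)) {
    fcp_lo[j] <- gs_lower_prob(state, times[j], lower[j], theta)
    fcp_up[j] <- gs_upper_prob(state, times[j], upper[j], theta)
    state <- gs_advance(state, times[j], lower[j], upper[j], theta, nodes)
  }
  out <- tibble::tibble(
    look = seq_len(k), t = times, lower = lower, upper = upper,
    fcp_lower = fcp_lo, fcp_upper = fcp_up
  )
  structure(out,
    class = c("crossing_probs", class(out)),
    p_continue = gs_mass(state), theta = theta
  )
}

#' @export
glance.crossing_probs <- function(x, ...) {
  tibble::tibble(
    theta = attr(x, "theta"),
    p_lower = sum(x$fcp_lower),
    p_upper = sum(x$fcp_upper),
    p_continue = attr(x, "p_continue")
  )
}

#' Efficacy (upper) boundaries from an alpha spending function
#'
#' Solves, look by look and under zero drift, for the upper z-score
#' boundaries whose first-crossing probabilities match the increments of the
#' alpha spending function. The lower boundary is ignored (non-binding
#' futility convention), so the type I error rate is controlled whether or
#' not a futility guideline is obeyed.
#'
#' @inheritParams crossing_probabilities
#' @param alpha_spec A [spending()] specification for the one-sided type I
#'   error; defaults to O'Brien-Fleming-like spending of `alpha`.
#' @param alpha One-sided type I error; used only to build the default
#'   `alpha_spec`.
#' @return Numeric vector of upper z-boundaries, one per look. A look with a
#'   zero spending increment gets an `Inf` boundary.
#' @examples
#' alpha_boundaries(c(0.25, 0.5, 0.75, 1)) # 4.3326 2.9631 2.3590 2.0141
#' @export
alpha_boundaries <- function(times, alpha_spec = NULL, alpha = 0.025,
                             nodes = GS_NODES) {
  validate_schedule(times)
  alpha_spec <- alpha_spec %||% spending("obf", total = alpha)
  if (alpha_spec$total >= 0.5) abort_domain("total alpha must be below 0.5.")
  incs <- diff(c(0, spend(alpha_spec, times)))
  k <- length(times)
  u <- numeric(k)
  state <- NULL
  for (j in seq_len(k)) {
    if (incs[j] < 1e-15) {
      u[j] <- Inf
    } else if (is.null(state)) {
      u[j] <- stats::qnorm(incs[j], lower.tail = FALSE)
    } else {
      f <- function(uu) gs_upper_prob(state, times[j], uu, 0) - incs[j]
      u[j] <- stats::uniroot(f, c(-8, 10), tol = 1e-12)$root
    }
    state <- gs_advance(state, times[j], -Inf, u[j], 0, nodes)
  }
  u
}

#' Futility boundaries and drift from a beta spending function
#'
#' Couples the lower (futility) boundary derivation to a calibration of the
#' drift parameter. For a candidate drift, lower boundaries at the interim
#' looks are solved so that the first-lower-crossing probabilities (with the
#' given efficacy boundaries respected) equal the beta-spending increments;
#' the final lower boundary is set equal to the final upper boundary so the
#' trial ends with an unambiguous conclusion. The drift is then found by
#' bisection so that the total type II error rate — all interim futility
#' crossings plus failing the final test without a prior efficacy crossing —
#' equals the total beta to be spent. The squared ratio of two calibrated
#' drifts is the relative sample size the two spending choices require.
#'
#' @inheritParams crossing_probabilities
#' @param beta_spec A [spending()] specification for the type II error.
#' @param upper Upper z-boundaries per look, e.g. from [alpha_boundaries()];
#'   by default derived from O'Brien-Fleming-like spending at `alpha`.
#' @param alpha One-sided type I error used for the default `upper`.
#' @param theta_interval Search bracket for the drift.
#' @param tol Absolute bisection tolerance on the drift.
#' @return An object of class `gs_design`: a list with a boundary tibble
#'   (`look`, `t`, `lower_z`, `upper_z`, `cum_beta_spent`, `cum_alpha_spent`),
#'   the calibrated `theta`, the achieved total type II error, and the two
#'   spending specifications. Use [tidy()], [glance()] and [autoplot()].
#' @examples
#' \donttest{
#' des <- gs_futility_design(c(0.25, 0.5, 0.75, 1),
#'                           beta_spec = spending("hsd", 0.15, gamma = -4))
#' tidy(des)
#' glance(des)
#' }
#' @export
gs_futility_design <- function(times, beta_spec, upper = NULL, alpha = 0.025,
                               theta_interval = c(0.5, 8), tol = 1e-8,
                               nodes = GS_NODES) {
  validate_schedule(times)
  stopifnot(inherits(beta_spec, "spending_spec"))
  k <- length(times)
  if (k < 2) abort_domain("A futility design needs at least two looks.")
  alpha_spec <- spending("obf", total = alpha)
  if (is.null(upper)) upper <- alpha_boundaries(times, alpha_spec, nodes = nodes)
  if (length(upper) != k) abort_domain("`upper` must have one entry per look.")
  incs <- diff(c(0, spend(beta_spec, times)))

  solve_lowers <- function(theta) {
    l <- numeric(k)
    ach <- numeric(k)
    clamped <- logical(k)
    state <- NULL
    for (j in seq_len(k - 1)) {
      hi <- min(upper[j], theta * sqrt(times[j]) + 9)
      lo <- theta * sqrt(times[j]) - 14
      f <- function(ll) gs_lower_prob(state, times[j], ll, theta) - incs[j]
      if (f(hi) < 0) {
        # spending increment exceeds the mass available below the efficacy
        # bound: aggressive-spending infeasibility, clamp to the upper bound
        l[j] <- upper[j]
        ach[j] <- gs_lower_prob(state, times[j], min(upper[j], hi), theta)
        clamped[j] <- TRUE
      } else {
        l[j] <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
        ach[j] <- incs[j]
      }
      state <- gs_advance(state, times[j], l[j], upper[j], theta, nodes)
    }
    l[k] <- upper[k]
    ach[k] <- gs_lower_prob(state, times[k], l[k], theta)
    list(lower = l, per_look = ach, total = sum(ach), clamped = clamped)
  }

  total_beta <- beta_spec$total
  lo <- theta_interval[1]
  hi <- theta_interval[2]
  f_lo <- solve_lowers(lo)$total - total_beta
  f_hi <- solve_lowers(hi)$total - total_beta
  if (f_lo < 0 || f_hi > 0) {
    abort_domain("drift bracket does not contain a solution; widen `theta_interval`.")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (solve_lowers(mid)$total > total_beta) lo <- mid else hi <- mid
  }
  theta <- (lo + hi) / 2
  sol <- solve_lowers(theta)
  if (any(sol$clamped)) {
    warning("beta spending increment(s) infeasible at look(s) ",
            paste(which(sol$clamped), collapse = ", "),
            "; lower boundary clamped to the efficacy boundary.")
  }
  boundaries <- tibble::tibble(
    look = seq_len(k), t = times,
    lower_z = sol$lower, upper_z = upper,
    cum_beta_spent = cumsum(sol$per_look),
    cum_alpha_spent = spend(alpha_spec, times)
  )
  structure(
    list(
      boundaries = boundaries, theta = theta,
      achieved_beta = sol$total, target_beta = total_beta,
      power = 1 - total_beta,
      beta_spec = beta_spec, alpha_spec = alpha_spec, clamped = sol$clamped
    ),
    class = "gs_design"
  )
}

#' @export
print.gs_design <- function(x, ...) {
  cat(sprintf(
    "<gs_design> %d looks, calibrated drift = %.4f (power %.3f at the final test)\n",
    nrow(x$boundaries), x$theta, 1 - x$achieved_beta
  ))
  print(x$boundaries)
  invisible(x)
}

#' @export
tidy.gs_design <- function(x, ...) x$boundaries

#' @export
glance.gs_design <- function(x, ...) {
  tibble::tibble(
    n_looks = nrow(x$boundaries),
    theta = x$theta,
    target_beta = x$target_beta,
    achieved_beta = x$achieved_beta,
    total_alpha = x$alpha_spec$total,
    any_clamped = any(x$clamped)
  )
}

#' Plot group-sequential boundaries
#'
#' @param object A [gs_futility_design()] result.
#' @param ... Unused.
#' @return A ggplot of the lower and upper z-boundaries over information time.
#' @export
autoplot.gs_design <- function(object, ...) {
  df <- tidyr::pivot_longer(object$boundaries, c("lower_z", "upper_z"),
                            names_to = "boundary", values_to = "z")
  df$boundary <- ifelse(df$boundary == "lower_z", "futility (lower)",
                        "efficacy (upper)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$z,
                                   colour = .data$boundary)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "information fraction", y = "z-score boundary", colour = NULL,
      title = sprintf("Group-sequential boundaries (drift %.3f)", object$theta)
    )
}
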