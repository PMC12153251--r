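#' Error spending functions
#'
#' Constructs a spending specification: a nondecreasing function of
#' information time prescribing the cumulative type I (alpha) or type II
#' (beta) error spent by each analysis, with `spend(0) = 0` and
#' `spend(1) = total`.
#'
#' Families:
#' * `"obf"` — the O'Brien-Fleming-like spending function
#'   `total_spend(t) = 2 * (1 - pnorm(qnorm(1 - total/2) / sqrt(t)))`. Very
#'   conservative early for small totals (alpha spending); for beta totals in
#'   the usual 0.10-0.20 range it accelerates earlier.
#' * `"hsd"` — the Hwang-Shih-DeCani (gamma) family
#'   `total * (1 - exp(-gamma * t)) / (1 - exp(-gamma))`. Negative `gamma`
#'   spends conservatively (e.g. -4), positive aggressively (e.g. +2).
#'   `gamma = 0` is the removable singularity and is defined by its limit,
#'   linear spending `total * t`.
#' * `"custom"` — a user-supplied function of `t` returning cumulative spend
#'   (checked at the endpoints).
#'
#' @param family One of `"obf"`, `"hsd"`, `"custom"`.
#' @param total Total error to spend (the one-sided alpha, or beta).
#' @param gamma Hwang-Shih-DeCani parameter; required for `family = "hsd"`.
#' @param fn Cumulative spending function for `family = "custom"`.
#' @return An object of class `spending_spec`.
#' @examples
#' sf <- spending("hsd", total = 0.15, gamma = -4)
#' spend(sf, c(0.25, 0.5, 0.75, 1))
#' @export
spending <- function(family = c("obf", "hsd", "custom"), total, gamma = NULL,
                     fn = NULL) {
  family <- match.arg(family)
  check_prob(total, "total")
  if (family == "hsd" && is.null(gamma)) {
    abort_domain("`gamma` is required for the Hwang-Shih-DeCani family.")
  }
  if (family == "custom") {
    if (!is.function(fn)) abort_domain("`fn` is required for family = \"custom\".")
    if (abs(fn(0)) > 1e-12 || abs(fn(1) - total) > 1e-8) {
      abort_domain("custom spending must satisfy fn(0) = 0 and fn(1) = total.")
    }
  }
  structure(
    list(family = family, total = total, gamma = gamma, fn = fn),
    class = "spending_spec"
  )
}

#' @export
print.spending_spec <- function(x, ...) {
  lab <- switch(x$family,
    obf = "O'Brien-Fleming-like",
    hsd = sprintf("Hwang-Shih-DeCani (gamma = %g)", x$gamma),
    custom = "custom"
  )
  cat(sprintf("<spending_spec> %s, total = %g\n", lab, x$total))
  invisible(x)
}

#' Cumulative error spent by information time t
#'
#' @param spec A [spending()] specification.
#' @param t Information fraction(s) in `[0, 1]`.
#' @return Cumulative spent error at each `t`.
#' @rdname spending
#' @export
spend <- function(spec, t) {
  stopifnot(inherits(spec, "spending_spec"))
  if (!is.numeric(t) || anyNA(t) || any(t < 0 | t > 1)) {
    abort_domain("`t` must lie in [0, 1].")
  }
  out <- switch(spec$family,
    obf = {
      zq <- stats::qnorm(1 - spec$total / 2)
      ifelse(t == 0, 0, 2 * (1 - stats::pnorm(zq / sqrt(pmax(t, 1e-300)))))
    },
    hsd = {
      g <- spec$gamma
      if (abs(g) < 1e-12) {
        spec$total * t
      } else {
        spec$total * (1 - exp(-g * t)) / (1 - exp(-g))
      }
    },
    custom = vapply(t, spec$fn, numeric(1))
  )
  pmin(pmax(out, 0), spec$total)
}

#' Plot a spending function
#'
#' @param object A [spending()] specification.
#' @param ... Unused.
#' @return A ggplot showing cumulative spend against information time.
#' @export
autoplot.spending_spec <- function(object, ...) {
  tt <- seq(0, 1, by = 0.01)
  df <- tibble::tibble(t = tt, spent = spend(object, tt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$spent)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "information fraction",
      y = "cumulative error spent",
      title = sprintf("Spending function (total = %g)", object$total)
    )
}
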