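# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# stop with a classed condition so callers/tests can distinguish domain errors
abort_domain <- function(msg) {
  rlang::abort(msg, class = "futilitymon_domain_error")
}

check_prob <- function(x, name, open_lower = TRUE, open_upper = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_domain(sprintf("`%s` must be numeric and non-missing.", name))
  }
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (!all(lo_ok & hi_ok)) {
    abort_domain(sprintf(
      "`%s` must lie in %s0, 1%s.", name,
      if (open_lower) "(" else "[", if (open_upper) ")" else "]"
    ))
  }
  invisible(x)
}

check_fraction <- function(t, name = "t", allow_one = TRUE) {
  if (!is.numeric(t) || anyNA(t)) {
    abort_domain(sprintf("`%s` must be numeric and non-missing.", name))
  }
  hi_ok <- if (allow_one) t <= 1 else t < 1
  if (!all(t > 0 & hi_ok)) {
    abort_domain(sprintf(
      "`%s` is an information fraction and must lie in (0, 1%s.",
      name, if (allow_one) "]" else ")"
    ))
  }
  invisible(t)
}

# run `expr` under `seed` if supplied, otherwise with the current RNG state
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# default critical value: the paper convention of monitoring against 1.96
# (one-sided alpha 0.025); overridable everywhere
default_z_crit <- 1.96
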