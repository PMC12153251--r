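test_that("interim_state derives the missing scale and enforces invariants", {
  st <- interim_state(t = c(0.25, 0.5), z = c(1, 0.3))
  expect_equal(st$b, sqrt(st$t) * st$z, tolerance = 1e-14)
  st2 <- interim_state(t = 0.5, b = 0.212)
  expect_equal(st2$z, 0.212 / sqrt(0.5), tolerance = 1e-12)
  expect_error(interim_state(t = 0), class = "futilitymon_domain_error")
  expect_error(interim_state(t = 1.2, z = 1), class = "futilitymon_domain_error")
  expect_error(interim_state(t = 0.5, z = 1, b = 0.9),
               class = "futilitymon_domain_error")
  expect_error(interim_state(t = 0.5), class = "futilitymon_domain_error")
})

test_that("information_fraction reproduces event-count ratios", {
  expect_equal(round(information_fraction(346, 713), 3), 0.485)
  expect_equal(information_fraction(713, 713), 1)
  expect_equal(information_fraction(606, 1212), 0.5)
  expect_error(information_fraction(0, 10), class = "futilitymon_domain_error")
  expect_error(information_fraction(11, 10), class = "futilitymon_domain_error")
})

test_that("b_value matches sqrt(t) * z and passes z through at t = 1", {
  expect_equal(round(b_value(0.5, 0.3), 3), 0.212)
  expect_identical(b_value(1, 2.1), 2.1)
  expect_equal(round(b_value(0.485, 0.733), 4), 0.5105)
  expect_error(b_value(1.5, 1), class = "futilitymon_domain_error")
})

test_that("drift-power map gives the standard design drifts and round-trips", {
  expect_equal(round(drift_from_power(c(0.80, 0.85, 0.90)), 2),
               c(2.80, 3.00, 3.24))
  p <- seq(0.05, 0.99, by = 0.01)
  expect_equal(power_from_drift(drift_from_power(p)), p, tolerance = 1e-10)
  # null drift recovers the one-sided alpha
  expect_equal(power_from_drift(0, z_crit = qnorm(0.975)), 0.025,
               tolerance = 1e-10)
})

test_that("conditional power reproduces the worked monitoring examples", {
  s <- interim_state(0.5, z = 0.3)
  expect_equal(round(conditional_power(s, theta = 3.00)$cp, 2), 0.36)
  trend <- current_trend_drift(s)$theta_trend
  expect_equal(trend, 0.424, tolerance = 1e-3)
  expect_equal(round(conditional_power(s, theta = trend)$cp, 2), 0.01)
  s0 <- interim_state(0.5, z = 0)
  expect_equal(round(conditional_power(s0, theta = 3.00)$cp, 3), 0.258)
  expect_equal(round(conditional_power(s0, theta = 2.80)$cp, 3), 0.214)
  expect_error(conditional_power(interim_state(1, z = 2), theta = 3),
               class = "futilitymon_domain_error")
})

test_that("conditional power is monotone in z and theta, with the t -> 0 limit", {
  z <- seq(-2, 3, by = 0.25)
  cp_z <- conditional_power(interim_state(rep(0.4, length(z)), z = z), 3)$cp
  expect_true(all(diff(cp_z) > 0))
  th <- seq(0, 5, by = 0.25)
  cp_th <- vapply(th, function(h) {
    conditional_power(interim_state(0.4, z = 0.5), h)$cp
  }, numeric(1))
  expect_true(all(diff(cp_th) > 0))
  # as t -> 0 with z fixed, CP approaches the unconditional power
  cp_small <- conditional_power(interim_state(1e-8, z = 0.5), 3.24)$cp
  expect_equal(cp_small, power_from_drift(3.24), tolerance = 1e-3)
})

test_that("current trend drift is B(t)/t, the final z at t = 1", {
  expect_equal(current_trend_drift(interim_state(0.5, b = 0.212))$theta_trend,
               0.424)
  expect_equal(current_trend_drift(interim_state(1, z = 1.7))$theta_trend, 1.7)
  expect_equal(current_trend_drift(interim_state(0.25, z = 1))$theta_trend, 2)
})

test_that("reverse conditional power matches its closed form and median", {
  expect_equal(reverse_conditional_power(interim_state(0.5, z = 0))$rcp,
               pnorm(-1.96), tolerance = 1e-12)
  expect_equal(round(
    reverse_conditional_power(interim_state(0.485, z = 0.733))$rcp, 3), 0.189)
  # the conditional median: z with B(t) at the conditional mean 1.96 * t
  for (t in c(0.2, 0.5, 0.8)) {
    expect_equal(
      reverse_conditional_power(interim_state(t, z = 1.96 * sqrt(t)))$rcp,
      0.5, tolerance = 1e-12)
  }
  z <- seq(-2, 2, by = 0.2)
  rcp <- reverse_conditional_power(interim_state(rep(0.5, length(z)), z = z))$rcp
  expect_true(all(diff(rcp) > 0))
})

test_that("PPoS reduces to conditional power at a point prior and compromises", {
  grid <- expand.grid(t = c(0.2, 0.5, 0.8), z = c(-1, 0, 0.5, 2))
  st <- interim_state(grid$t, z = grid$z)
  expect_equal(ppos(st, theta0 = 3, sigma0_sq = 0)$ppos,
               conditional_power(st, theta = 3)$cp, tolerance = 1e-12)
  expect_equal(ppos(interim_state(0.5, z = 0), 0, 0)$ppos,
               pnorm(-1.96 / sqrt(0.5)), tolerance = 1e-12)
  # diffuse prior pulls PPoS between CP under hypothesis and under trend
  s <- interim_state(0.5, z = 0.3)
  cp_hyp <- conditional_power(s, 3)$cp
  cp_trend <- conditional_power(s, current_trend_drift(s)$theta_trend)$cp
  pp <- ppos(s, theta0 = 3, sigma0_sq = 4)$ppos
  expect_gt(pp, cp_trend)
  expect_lt(pp, cp_hyp)
})

test_that("probability outputs stay in [0, 1] across a wide input grid", {
  grid <- expand.grid(t = c(0.01, 0.3, 0.7, 0.99), z = c(-5, 0, 5),
                      theta = c(-2, 0, 4))
  st <- interim_state(grid$t, z = grid$z)
  vals <- c(conditional_power(st, grid$theta)$cp,
            reverse_conditional_power(st)$rcp,
            ppos(st, theta0 = grid$theta, sigma0_sq = 2)$ppos)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("continuous-curtailment type II bound is beta / (1 - Gamma)", {
  expect_equal(continuous_curtailment_beta(0.10, 0.20), 0.125)
  expect_equal(continuous_curtailment_beta(0.13, 0), 0.13)
  expect_equal(continuous_curtailment_beta(0.15, 0.20), 0.1875)
  expect_error(continuous_curtailment_beta(0.1, 1),
               class = "futilitymon_domain_error")
})
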