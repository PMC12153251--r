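test_that("single-look crossing probabilities match closed forms", {
  cp <- crossing_probabilities(1, lower = 1.96, upper = 1.96, theta = 3.2416)
  expect_equal(cp$fcp_lower, pnorm(1.96 - 3.2416), tolerance = 1e-10)
  expect_equal(round(cp$fcp_lower, 3), 0.100)
  expect_equal(attr(cp, "p_continue"), 0)

  cp0 <- crossing_probabilities(1, lower = -Inf, upper = qnorm(0.975),
                                theta = 0)
  expect_equal(cp0$fcp_upper, 0.025, tolerance = 1e-12)
  expect_equal(cp0$fcp_lower, 0)
})

test_that("crossing probabilities conserve total mass", {
  cp <- crossing_probabilities(c(0.2, 0.45, 0.8, 1),
                               lower = c(-1, -0.2, 0.5, 2.0141),
                               upper = c(4.33, 2.96, 2.36, 2.0141),
                               theta = 1.7)
  tot <- sum(cp$fcp_lower) + sum(cp$fcp_upper) + attr(cp, "p_continue")
  expect_equal(tot, 1, tolerance = 1e-8)
})

test_that("alpha boundaries reproduce O'Brien-Fleming-like values and spend alpha", {
  u <- alpha_boundaries(c(0.25, 0.5, 0.75, 1))
  expect_equal(round(u, 4), c(4.3326, 2.9631, 2.3590, 2.0141))
  expect_equal(alpha_boundaries(1), qnorm(0.975), tolerance = 1e-10)

  # round-trip: cumulative upper crossings equal the spending function
  sp <- spending("obf", 0.025)
  cp <- crossing_probabilities(c(0.25, 0.5, 0.75, 1),
                               lower = rep(-Inf, 4), upper = u, theta = 0)
  expect_equal(cumsum(cp$fcp_upper), spend(sp, c(0.25, 0.5, 0.75, 1)),
               tolerance = 1e-6)
  expect_equal(sum(cp$fcp_upper), 0.025, tolerance = 1e-6)

  # two-look self-consistency at unequal times
  u2 <- alpha_boundaries(c(0.4, 1))
  cp2 <- crossing_probabilities(c(0.4, 1), rep(-Inf, 2), u2, 0)
  expect_equal(sum(cp2$fcp_upper), 0.025, tolerance = 1e-8)
})

test_that("cumulative crossings are invariant to a pass-through look", {
  base <- crossing_probabilities(c(0.25, 0.5, 1),
                                 lower = c(-0.5, 0.2, 1.96),
                                 upper = c(4, 3, 1.96), theta = 2.5)
  padded <- crossing_probabilities(c(0.25, 0.5, 0.75, 1),
                                   lower = c(-0.5, 0.2, -Inf, 1.96),
                                   upper = c(4, 3, Inf, 1.96), theta = 2.5)
  expect_equal(sum(padded$fcp_lower), sum(base$fcp_lower), tolerance = 1e-8)
  expect_equal(sum(padded$fcp_upper), sum(base$fcp_upper), tolerance = 1e-8)
  expect_equal(padded$fcp_lower[1:2], base$fcp_lower[1:2], tolerance = 1e-10)
})

test_that("numerical integration agrees with the Monte-Carlo oracle", {
  times <- c(0.15, 0.4, 0.65, 0.85, 1)
  lower <- c(-1.2, -0.3, 0.4, 1.0, 1.96)
  upper <- c(3.8, 3.1, 2.6, 2.2, 1.96)
  for (theta in c(0, 1.5, 3.1)) {
    cp <- crossing_probabilities(times, lower, upper, theta)
    pb <- simulate_paths(times, theta, n_rep = 2e5, seed = 4123 + theta * 10)
    eo <- glance(empirical_oc(pb, lower, upper))
    expect_lt(abs(sum(cp$fcp_lower) - eo$p_lower), 3 * eo$se_lower + 1e-12)
    expect_lt(abs(sum(cp$fcp_upper) - eo$p_upper), 3 * eo$se_upper + 1e-12)
  }
})

test_that("beta-boundary solver hits its spending targets and final tie", {
  times <- c(0.25, 0.5, 0.75, 1)
  for (g in c(-4, -2, 2)) {
    sp <- spending("hsd", 0.15, gamma = g)
    des <- gs_futility_design(times, sp)
    bd <- tidy(des)
    # final lower boundary equals the final upper boundary
    expect_equal(bd$lower_z[4], bd$upper_z[4], tolerance = 1e-12)
    # lower boundaries increase over information time
    expect_true(all(diff(bd$lower_z) > 0))
    # first-lower-crossing probabilities reproduce the spending increments
    cp <- crossing_probabilities(times, bd$lower_z, bd$upper_z, des$theta)
    expect_equal(cumsum(cp$fcp_lower)[1:3], spend(sp, times)[1:3],
                 tolerance = 1e-5)
    # total type II error equals the spending total
    expect_equal(sum(cp$fcp_lower), 0.15, tolerance = 1e-5)
    expect_equal(des$achieved_beta, 0.15, tolerance = 1e-6)
  }
})

test_that("conservative beta spending needs only slightly more drift than no monitoring", {
  des <- gs_futility_design(c(0.25, 0.5, 0.75, 1),
                            spending("hsd", 0.15, gamma = -4))
  expect_gt(des$theta, 3.00) # the no-monitoring drift for 85% power
  expect_lt(des$theta, 3.10)
})

test_that("Monte-Carlo paths confirm the calibrated design type II error", {
  des <- gs_futility_design(c(0.25, 0.5, 0.75, 1),
                            spending("hsd", 0.15, gamma = -4))
  pb <- simulate_paths(c(0.25, 0.5, 0.75, 1), des$theta, n_rep = 2e5,
                       seed = 777)
  eo <- glance(empirical_oc(pb, tidy(des)$lower_z, tidy(des)$upper_z))
  expect_lt(abs(eo$p_lower - 0.15), 3 * eo$se_lower)
})

test_that("engine rejects malformed schedules and brackets", {
  expect_error(crossing_probabilities(numeric(0), numeric(0), numeric(0), 1),
               class = "futilitymon_domain_error")
  expect_error(crossing_probabilities(c(0.5, 0.5, 1), rep(-Inf, 3),
                                      rep(Inf, 3), 1),
               class = "futilitymon_domain_error")
  expect_error(crossing_probabilities(0.5, lower = 1, upper = 0, theta = 1),
               class = "futilitymon_domain_error")
  expect_error(gs_futility_design(c(0.5, 1), spending("hsd", 0.15, gamma = -4),
                                  theta_interval = c(7.5, 8)),
               class = "futilitymon_domain_error")
})
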