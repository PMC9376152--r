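test_that("observed recovery time detects the first resource upturn", {
  pars <- baseline_params()
  # consumer-free below n*: monotone increase from the first pulse
  expect_identical(recovery_time_observed(cr_simulate(c(0, 1), pars, 10)), 1L)
  # consumer-free above n*: strictly decreasing -> sentinel
  expect_identical(recovery_time_observed(cr_simulate(c(0, 20), pars, 50)),
                   NA_integer_)
  # resource extinct: undefined
  expect_error(recovery_time_observed(cr_simulate(c(1, 0), pars, 10)),
               "undefined")
})

test_that("analytic recovery estimate follows log(p0)/(-log delta_p)", {
  pars <- baseline_params()
  expect_equal(recovery_time_estimate(pars, 100), 43.708690653565665,
               tolerance = 1e-13)
  expect_error(recovery_time_estimate(pars, 1), "exceed 1")
  # linear in log p0: squaring p0 doubles the estimate
  expect_equal(recovery_time_estimate(pars, 50^2),
               2 * recovery_time_estimate(pars, 50), tolerance = 1e-12)
})

test_that("recovery time grows with initial consumer density at the theorem rate", {
  pars <- baseline_params()
  p0s <- 10^seq(1, 6, length.out = 12)
  obs <- vapply(p0s, function(p0)
    as.numeric(recovery_time_observed(cr_simulate(c(p0, 1), pars, 2000))),
    numeric(1))
  expect_true(all(diff(obs) > 0))
  # epsilon = 1/p0: slope of time against log(1/epsilon) = log(p0)
  sl <- scaling_slope(-log(p0s), obs)
  expect_lt(abs(sl$slope - 9.4912215810299030) / 9.4912215810299030, 0.15)
})

test_that("observed escape time fires at the resource crash, not the drift", {
  pars3 <- baseline_params(gamma_p = 3)
  nstar <- carrying_capacity(pars3)
  tr <- cr_simulate(c(1e-4, nstar - 1e-4), pars3, 5000)
  tau <- escape_time_observed(tr)
  expect_gt(tau, 100)  # crawl-by near (0, n*) lasts many pulses
  expect_lt(tr$n[tau + 1L], 0.5 * tr$n[1L])
  # the strict-direction reading sees the O(p0) recruitment drift at once
  expect_identical(escape_time_observed(tr, method = "direction"), 1L)
  # subcritical: consumer decays, resource never halves -> sentinel
  pars1 <- baseline_params()
  expect_identical(
    escape_time_observed(cr_simulate(c(1e-6, 9 - 1e-6), pars1, 3000)),
    NA_integer_)
  # immediate crash reads as pulse 1 under the direction method
  expect_identical(
    escape_time_observed(cr_simulate(c(10, 1), pars1, 10),
                         method = "direction"), 1L)
})

test_that("analytic escape estimate follows log(1/eps)/log(lambda1)", {
  pars3 <- baseline_params(gamma_p = 3)
  # log(1000)/log(1.0242693...) evaluated by hand
  expect_equal(escape_time_estimate(pars3, 1e-3), 288.06893607578370,
               tolerance = 1e-12)
  # pole at the bifurcation: estimate grows as gamma_p decreases to gamma_p*
  expect_gt(escape_time_estimate(baseline_params(gamma_p = 2.5), 1e-3),
            escape_time_estimate(pars3, 1e-3))
  expect_error(escape_time_estimate(baseline_params(gamma_p = 1), 1e-3),
               "cannot invade")
  expect_error(escape_time_estimate(pars3, 1.5), "0, 1")
})

test_that("escape time scales with log(1/eps) at the invasion-eigenvalue rate", {
  pars3 <- baseline_params(gamma_p = 3)
  nstar <- carrying_capacity(pars3)
  eps <- 10^seq(-8, -2, length.out = 12)
  obs <- vapply(eps, function(e)
    as.numeric(escape_time_observed(cr_simulate(c(e, nstar - e), pars3, 5000))),
    numeric(1))
  sl <- scaling_slope(log(eps), obs)
  target <- 1 / log(lambda1(pars3))
  expect_lt(abs(sl$slope - target) / target, 0.15)
})

test_that("ghost escape time marks entry into the monotone basin", {
  gps <- bifurcation_value(baseline_params())
  pars <- baseline_params(gamma_p = 0.9912 * gps)
  cat0 <- equilibrium_catalog(pars)

  # initial state already past the upper saddle -> 0
  tr0 <- cr_simulate(c(0.001, 8.95), pars, 10)
  expect_identical(ghost_escape_time(tr0, cat0), 0L)

  tr <- cr_simulate(c(10, 1), pars, 10000)
  tau <- ghost_escape_time(tr, cat0)
  expect_false(is.na(tau))
  # after tau: resource non-decreasing, consumer non-increasing (log space,
  # ties at machine precision allowed)
  post <- which(tr$m >= tau)
  expect_true(all(diff(attr(tr, "ln")[post]) > -1e-12))
  expect_true(all(diff(attr(tr, "lp")[post]) < 1e-12))

  # undefined without a coexistence pair
  cat_none <- equilibrium_catalog(baseline_params(gamma_p = 0.3))
  expect_error(ghost_escape_time(tr, cat_none), "coexistence")
})

test_that("tau sweep produces escape times that grow toward the bifurcation", {
  base <- baseline_params()
  gps <- bifurcation_value(base)
  grid <- gps * 10^seq(-3, -1, length.out = 8)
  sw <- tau_sweep(base, epsilon_grid = grid, horizon = 2000)
  expect_identical(names(sw), c("epsilon", "gamma_p", "tau"))
  expect_true(all(sw$tau > 0))
  # tau decreases (statistically) as epsilon grows
  expect_lt(cor(sw$epsilon, sw$tau, method = "spearman"), 0)
  expect_error(tau_sweep(base, epsilon_grid = c(0.01, gps * 1.1)),
               "gamma_p\\*")
  # horizon too short for any escape
  expect_error(suppressWarnings(
    tau_sweep(base, epsilon_grid = grid[1:3], horizon = 20)), "horizon")
})

test_that("power-law fit recovers its own generating law", {
  eps <- 10^seq(-3, -1, length.out = 10)
  fit <- fit_power_law(data.frame(epsilon = eps, tau = round(50 * eps^-1.2)))
  expect_lt(abs(fit$A - 50) / 50, 0.05)
  expect_lt(abs(fit$B - 1.2) / 1.2, 0.05)
  expect_gt(fit$r_squared, 0.99)
  # constant tau -> flat exponent
  flat <- fit_power_law(data.frame(epsilon = eps, tau = rep(7, 10)))
  expect_equal(flat$B, 0, tolerance = 1e-12)
  expect_error(fit_power_law(data.frame(epsilon = eps[1:2], tau = c(1, 2))),
               "at least 3")
  expect_error(fit_power_law(data.frame(epsilon = rep(0.1, 4),
                                        tau = c(1, 2, 3, 4))), "degenerate")
})

test_that("scaling slope recovers an exact log law", {
  eps <- 10^seq(-6, -1, length.out = 9)
  times <- 12.5 * log(1 / eps) + 3
  sl <- scaling_slope(log(eps), times)
  expect_equal(sl$slope, 12.5, tolerance = 1e-10)
  expect_equal(sl$intercept, 3, tolerance = 1e-8)
  expect_error(scaling_slope(log(eps)[1:2], times[1:2]), "at least 3")
})
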