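test_that("carrying capacity matches the iteration oracle", {
  pars <- baseline_params()
  expect_equal(carrying_capacity(pars), 9, tolerance = 1e-14)
  # independent oracle: converge the consumer-free map
  n <- 1
  for (k in 1:1e4) n <- step_resource_only(n, pars)
  expect_equal(carrying_capacity(pars), n, tolerance = 1e-12)

  p2 <- cr_params(0.9, 0.5, 1, 1, 2.67, R = 1, check_group_defense = FALSE)
  expect_equal(carrying_capacity(p2), 1, tolerance = 1e-14)
  # boundary of self-replenishment: n* -> 0+
  p3 <- cr_params(0.9, 0.8, 1, 1, 2.67, R = 0.2 + 1e-9,
                  check_group_defense = FALSE)
  expect_lt(carrying_capacity(p3), 1e-7)
  expect_gt(carrying_capacity(p3), 0)
})

test_that("bifurcation value and invasion eigenvalue are consistent", {
  pars <- baseline_params()
  # (1 - 0.9) * (1 + 2.67 * 81) / 9 evaluated by hand
  expect_equal(bifurcation_value(pars), 2.4141111111111111, tolerance = 1e-14)
  expect_equal(lambda1(baseline_params(gamma_p = 3)), 1.0242693422929995,
               tolerance = 1e-14)
  # gamma_p -> 0+: lambda_1 -> delta_p
  expect_equal(lambda1(baseline_params(gamma_p = 1e-12)), 0.9,
               tolerance = 1e-11)
  # algebraic identity lambda_1(gamma_p = gamma_p*) = 1, across parameter space
  set.seed(5)
  for (i in 1:100) {
    base <- random_params()
    gps <- bifurcation_value(base)
    at_star <- cr_params(base$delta_p, base$delta_n, gamma_p = gps,
                         base$gamma_n, base$sigma, base$R,
                         check_group_defense = FALSE)
    expect_lt(abs(lambda1(at_star) - 1), 1e-12)
  }
})

test_that("coexistence pair exists below the bifurcation and solves the map", {
  # ghost-regime parameters: gamma_p = 0.9912 * gamma_p*
  pars <- baseline_params(gamma_p = 0.9912 * 2.4141111111111111)
  cp <- coexistence_pair(pars)
  expect_named(cp, c("coexistence_low", "coexistence_high"))
  # frozen 40-digit Newton-refined coordinates
  expect_equal(unname(cp$coexistence_low),
               c(1.0017974720886335, 0.041987587463887267), tolerance = 1e-9)
  expect_equal(unname(cp$coexistence_high),
               c(0.0078784083205481846, 8.9200608519867994), tolerance = 1e-9)
  for (eq in cp) {
    nxt <- cr_step(eq, pars)
    expect_lt(max(abs(nxt - eq)), 1e-10)
  }
})

test_that("coexistence pair vanishes without group defense or real roots", {
  expect_identical(coexistence_pair(
    cr_params(0.9, 0.8, 1, 1, sigma = 0, R = 2,
              check_group_defense = FALSE)), list())
  # negative discriminant: gamma_p^2 < 4 sigma (1 - delta_p)^2
  expect_identical(coexistence_pair(baseline_params(gamma_p = 0.3)), list())
})

test_that("analytic Jacobian matches central finite differences", {
  fd_jacobian <- function(s, pars) {
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- 1e-6 * max(1, abs(s[j]))
      up <- s; up[j] <- up[j] + h
      dn <- s; dn[j] <- dn[j] - h
      J[, j] <- (cr_step(up, pars) - cr_step(dn, pars)) / (2 * h)
    }
    J
  }
  set.seed(21)
  for (i in 1:100) {
    pars <- random_params()
    s <- c(10^runif(1, -3, 1.3), 10^runif(1, -3, 1.3))
    J <- cr_jacobian(s, pars)
    expect_lt(max(rel_err(J, fd_jacobian(s, pars))), 1e-5)
  }
})

test_that("Jacobian is triangular on the consumer axis with known spectrum", {
  pars <- baseline_params(gamma_p = 3)
  nstar <- carrying_capacity(pars)
  J <- cr_jacobian(c(0, nstar), pars)
  expect_identical(J["p_next", "n"], 0)
  ev <- sort(eigen(J, only.values = TRUE)$values)
  expect_equal(ev, sort(c(lambda1(pars), 0.8 + 2 / (1 + nstar)^2)),
               tolerance = 1e-12)
  # origin: eigenvalues delta_p and delta_n + R (> 1: extinction unstable)
  J0 <- cr_jacobian(c(0, 0), pars)
  expect_equal(sort(eigen(J0, only.values = TRUE)$values), c(0.9, 2.8),
               tolerance = 1e-14)
})

test_that("catalog classifies stability across the bifurcation", {
  below <- equilibrium_catalog(baseline_params(gamma_p = 1))
  expect_identical(below$equilibria$carrying_capacity$stability, "stable")
  # coexistence points below the bifurcation are unstable or saddles
  for (lab in c("coexistence_low", "coexistence_high"))
    expect_true(below$equilibria[[lab]]$stability %in%
                  c("unstable", "saddle"))

  above <- equilibrium_catalog(baseline_params(gamma_p = 3))
  stabs <- vapply(above$equilibria, `[[`, "", "stability")
  expect_false(any(stabs == "stable"))

  # extinction is never stable under self-replenishment (delta_n + R > 1)
  set.seed(31)
  for (i in 1:50) {
    cat0 <- equilibrium_catalog(random_params())
    expect_true(cat0$equilibria$extinction$stability %in%
                  c("saddle", "unstable"))
    expect_lte(length(cat0$equilibria), 4L)
    for (eq in cat0$equilibria) {
      resid <- max(abs(cr_step(eq$location, cat0$params) - eq$location))
      expect_lt(resid, 1e-10)
    }
  }
})

test_that("stability switch of (0, n*) is located exactly at gamma_p*", {
  base <- baseline_params()
  mod_max <- function(gp) {
    cat0 <- equilibrium_catalog(baseline_params(gamma_p = gp), tol = 0)
    max(cat0$equilibria$carrying_capacity$moduli)
  }
  lo <- 2; hi <- 3
  for (k in 1:60) {
    mid <- 0.5 * (lo + hi)
    if (mod_max(mid) < 1) lo <- mid else hi <- mid
  }
  expect_equal(0.5 * (lo + hi), bifurcation_value(base), tolerance = 1e-9)
})
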