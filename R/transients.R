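# Transient-time machinery: observed crawl-by times read off trajectories,
# their analytic log-scaling estimates, the ghost-attractor escape time,
# and the power-law fit of escape time against distance to the bifurcation.

# Strict direction changes are detected in log space; differences below
# .dir_tol are ties (no change), which suppresses spurious flips at
# machine precision.
.dir_tol <- 1e-12

# first index m >= 1 (pulse count) where the log-resource series moves in
# `direction` (+1 increase, -1 decrease); NA when it never does
.first_direction_change <- function(traj, direction) {
  ln <- attr(traj, "ln")
  if (is.null(ln)) ln <- log(traj$n)
  if (length(ln) < 2L)
    stop("trajectory must contain at least 2 states")
  if (any(ln == -Inf))
    stop("resource density hits 0 along the trajectory; ",
         "recovery/escape times are undefined")
  d <- diff(ln) * direction
  hit <- which(d > .dir_tol)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Observed resource recovery time
#'
#' The first pulse at which the resource density strictly increases,
#' \eqn{\min\{m \ge 1 : n_m > n_{m-1}\}}.  Along a crawl-by transient near
#' resource extinction (large initial consumer density), the resource
#' keeps shrinking until the consumer has decayed enough to release it;
#' this index marks the onset of recovery.
#'
#' @param traj a \code{cr_trajectory} from [cr_simulate()] with strictly
#'   positive resource throughout.
#' @return Integer pulse index, or \code{NA} if the resource never
#'   increases within the horizon.
#' @seealso [recovery_time_estimate()] for the analytic approximation.
#' @export
recovery_time_observed <- function(traj) {
  .first_direction_change(traj, +1)
}

#' Analytic crawl-by recovery time near resource extinction
#'
#' For initial consumer density \eqn{p_0} of order \eqn{1/\varepsilon}
#' (with \eqn{\varepsilon = 1/p_0 \ll 1}), the resource begins to recover
#' after approximately
#' \deqn{M = \frac{\log \varepsilon}{\log \delta_p}
#'         = \frac{\log p_0}{-\log \delta_p}}
#' pulses -- the time the consumer, decaying geometrically at rate
#' \eqn{\delta_p}, needs to fall to order one.  The order constant is
#' taken as 1.
#'
#' @param params a [cr_params()] object.
#' @param p0 initial consumer density, must exceed 1.
#' @return Estimated recovery time in pulses (positive real).
#' @examples
#' recovery_time_estimate(cr_params(0.9, 0.8, 1, 1, 2.67, 2), p0 = 100)
#' @export
recovery_time_estimate <- function(params, p0) {
  params <- .as_params(params)
  if (!is.numeric(p0) || length(p0) != 1L || !is.finite(p0) || p0 <= 1)
    stop("'p0' must exceed 1 (epsilon = 1/p0 must be small)")
  log(p0) / (-log(params$delta_p))
}

#' Observed consumer escape time from rarity
#'
#' The pulse at which the resource's decline becomes substantial: by
#' default the first \eqn{m} with \eqn{n_m < f \cdot n_0} (threshold
#' method, \eqn{f} = \code{frac}).  Starting from a rare consumer near the
#' resource-only equilibrium \eqn{(0, n^*)}, the resource crashes only
#' once the invading consumer has grown to order one; this index marks the
#' consumer's escape from rarity.
#'
#' The strict-direction alternative (\code{method = "direction"}: first
#' \eqn{m} with \eqn{n_m < n_{m-1}}) is also available, but it is
#' degenerate for this transient: the consumer suppresses recruitment at
#' first order in \eqn{p}, so the resource drifts down by an
#' \eqn{O(p_0)} amount from the very first pulse -- in either dynamical
#' regime -- and the first strict decrease is 1 regardless of how long the
#' crawl-by lasts.  The threshold method ignores that drift and fires only
#' when the crash proper arrives.
#'
#' @inheritParams recovery_time_observed
#' @param method \code{"threshold"} (default) or \code{"direction"}.
#' @param frac threshold fraction of the initial resource density
#'   (default 0.5; threshold method only).
#' @return Integer pulse index, or \code{NA} if the resource never crosses
#'   the threshold (never decreases, for \code{"direction"}) within the
#'   horizon.
#' @seealso [escape_time_estimate()]
#' @export
escape_time_observed <- function(traj, method = c("threshold", "direction"),
                                 frac = 0.5) {
  method <- match.arg(method)
  if (method == "direction") return(.first_direction_change(traj, -1))
  if (!is.numeric(frac) || length(frac) != 1L || !is.finite(frac) ||
      frac <= 0 || frac >= 1)
    stop("'frac' must lie in (0, 1)")
  ln <- attr(traj, "ln")
  if (is.null(ln)) ln <- log(traj$n)
  if (any(ln == -Inf))
    stop("resource density hits 0 along the trajectory; ",
         "recovery/escape times are undefined")
  hit <- which(ln < ln[1L] + log(frac))
  if (length(hit) == 0L) NA_integer_ else traj$m[hit[1L]]
}

#' Analytic crawl-by escape time near the resource-only equilibrium
#'
#' For \eqn{\gamma_p > \gamma_p^*} and initial state
#' \eqn{(p_0, n_0) = (\varepsilon, n^* - \varepsilon)} with
#' \eqn{0 < \varepsilon \ll 1}, the resource starts decaying after
#' approximately
#' \deqn{M = \frac{\log(1/\varepsilon)}{\log \lambda_1}}
#' pulses, where \eqn{\lambda_1 > 1} is the invasion eigenvalue
#' ([lambda1()]).  The order constant is taken as 1.  The estimate
#' diverges as \eqn{\gamma_p \downarrow \gamma_p^*} (the crawl-by grows
#' without bound at the bifurcation).
#'
#' @param params a [cr_params()] object with
#'   \eqn{\gamma_p > \gamma_p^*}.
#' @param epsilon initial consumer density (the perturbation size), in
#'   (0, 1).
#' @return Estimated escape time in pulses (positive real).
#' @export
escape_time_estimate <- function(params, epsilon) {
  params <- .as_params(params)
  lam <- lambda1(params)
  if (lam <= 1)
    stop(sprintf(
      "escape requires gamma_p > gamma_p* (lambda_1 = %g <= 1): consumer cannot invade",
      lam))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0 || epsilon >= 1)
    stop("'epsilon' must lie in (0, 1)")
  log(1 / epsilon) / log(lam)
}

#' Escape time from the ghost limit cycle
#'
#' Just below the bifurcation (\eqn{\gamma_p < \gamma_p^*},
#' \eqn{\gamma_p^* - \gamma_p \ll 1}) the system oscillates for a long
#' time on a ghost of the consumer-resource cycle before converging to
#' \eqn{(0, n^*)}.  Once the state enters the region
#' \eqn{\{n > n^{\wedge},\, p < p^{\wedge}\}} -- past the upper
#' coexistence saddle \eqn{(p^{\wedge}, n^{\wedge})} -- the resource
#' increases and the consumer decreases monotonically ever after, so the
#' escape time is
#' \deqn{\tau = \min\{M : n_M > n^{\wedge},\; p_M < p^{\wedge}\}.}
#'
#' @param traj a \code{cr_trajectory} simulated under the same parameters
#'   as \code{cat}.
#' @param cat an [equilibrium_catalog()] whose coexistence pair is
#'   nonempty.
#' @return Integer pulse index (possibly 0 if the initial state already
#'   qualifies), or \code{NA} if the trajectory never escapes within the
#'   horizon.
#' @export
ghost_escape_time <- function(traj, cat) {
  if (!inherits(cat, "cr_equilibrium_catalog"))
    stop("'cat' must be an equilibrium catalog")
  hi <- cat$equilibria[["coexistence_high"]]
  if (is.null(hi))
    stop("catalog has no coexistence pair; the ghost escape criterion is undefined")
  p_hat <- hi$location[["p"]]; n_hat <- hi$location[["n"]]
  hit <- which(traj$n > n_hat & traj$p < p_hat)
  if (length(hit) == 0L) NA_integer_ else traj$m[hit[1L]]
}

#' Sweep the ghost-attractor escape time toward the bifurcation
#'
#' For each \eqn{\varepsilon} in the grid, sets
#' \eqn{\gamma_p = \gamma_p^* - \varepsilon}, simulates from \code{s0} and
#' records the escape time \eqn{\tau} from the ghost cycle.  Escape times
#' grow as \eqn{\varepsilon} shrinks; [fit_power_law()] fits the power law
#' \eqn{\tau = A\varepsilon^{-B}} to the result.
#'
#' @param params_base a [cr_params()] object supplying every parameter
#'   except \code{gamma_p} (which the sweep overwrites).
#' @param epsilon_grid positive offsets below \eqn{\gamma_p^*}; default 12
#'   geometrically spaced values spanning
#'   \eqn{[10^{-3}, 10^{-1}]\,\gamma_p^*}.
#' @param s0 initial state (default \code{c(10, 1)}).
#' @param horizon pulses per simulation (default 50000).
#' @return A data frame with columns \code{epsilon}, \code{gamma_p},
#'   \code{tau}; grid points whose trajectory never escaped are dropped
#'   with a warning.  Errors if every point is dropped.
#' @export
tau_sweep <- function(params_base, epsilon_grid = NULL, s0 = c(10, 1),
                      horizon = 50000) {
  params_base <- .as_params(params_base)
  gps <- bifurcation_value(params_base)
  if (is.null(epsilon_grid))
    epsilon_grid <- gps * 10^seq(-3, -1, length.out = 12)
  if (any(epsilon_grid <= 0) || any(epsilon_grid >= gps))
    stop(sprintf("epsilon values must lie in (0, gamma_p* = %g)", gps))

  rows <- lapply(epsilon_grid, function(eps) {
    pars <- cr_params(params_base$delta_p, params_base$delta_n,
                      gamma_p = gps - eps,
                      params_base$gamma_n, params_base$sigma, params_base$R,
                      check_group_defense = FALSE)
    cat <- equilibrium_catalog(pars)
    tau <- ghost_escape_time(cr_simulate(s0, pars, horizon), cat)
    data.frame(epsilon = eps, gamma_p = gps - eps, tau = tau)
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$tau)))
    stop("no trajectory escaped the ghost attractor within the horizon; ",
         "increase 'horizon'")
  if (anyNA(out$tau))
    warning(sprintf("%d of %d grid points did not escape within horizon %d and were dropped",
                    sum(is.na(out$tau)), nrow(out), horizon))
  out <- out[!is.na(out$tau), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gamma_p_star") <- gps
  out
}

#' Fit the transient-time power law
#'
#' Ordinary least squares of \eqn{\log\tau} on \eqn{\log\varepsilon} for
#' the power law \eqn{\tau(\gamma_p) = A(\gamma_p^* - \gamma_p)^{-B}}:
#' the fitted intercept gives \eqn{A = e^{\mathrm{intercept}}} and slope
#' gives \eqn{B = -\mathrm{slope}}.
#'
#' @param sample a data frame with columns \code{epsilon}
#'   (\eqn{= \gamma_p^* - \gamma_p}, > 0) and \code{tau} (> 0), e.g. from
#'   [tau_sweep()]; at least 3 rows with non-degenerate epsilons.
#' @return An object of class \code{cr_powerlaw_fit}: list with \code{A},
#'   \code{B}, \code{r_squared}, \code{gamma_p_star} (when the sample
#'   carries it, else \code{NA}) and the \code{sample}.
#' @examples
#' eps <- 10^seq(-3, -1, length.out = 8)
#' fit_power_law(data.frame(epsilon = eps, tau = round(50 * eps^-1.2)))
#' @export
fit_power_law <- function(sample) {
  if (!all(c("epsilon", "tau") %in% names(sample)))
    stop("'sample' must have columns 'epsilon' and 'tau'")
  if (nrow(sample) < 3L)
    stop("need at least 3 (epsilon, tau) pairs to fit the power law")
  if (any(sample$epsilon <= 0) || any(sample$tau <= 0))
    stop("all epsilon and tau values must be positive")
  if (length(unique(sample$epsilon)) < 2L)
    stop("degenerate sample: all epsilon values are equal")
  fit <- stats::lm(log(tau) ~ log(epsilon), data = sample)
  co <- stats::coef(fit)
  # r^2 computed directly; a constant-tau sample (zero total variance) is a
  # perfect flat fit, reported as r^2 = 1
  ss_tot <- sum((log(sample$tau) - mean(log(sample$tau)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(list(A = exp(unname(co[1L])), B = -unname(co[2L]),
                 r_squared = r2,
                 gamma_p_star = attr(sample, "gamma_p_star") %||% NA_real_,
                 sample = sample),
            class = "cr_powerlaw_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cr_powerlaw_fit <- function(x, ...) {
  cat("Ghost-attractor transient-time power law  tau = A * epsilon^(-B)\n")
  cat(sprintf("  A = %.6g, B = %.6g, log-log r^2 = %.4f (%d points)\n",
              x$A, x$B, x$r_squared, nrow(x$sample)))
  invisible(x)
}

#' Log-scaling slope of observed transient times
#'
#' Least-squares slope and intercept of observed transient time against
#' \eqn{\log(1/\varepsilon)}, used to verify the crawl-by scalings: the
#' slope should approach \eqn{1/(-\log\delta_p)} for the recovery
#' transient (\eqn{\varepsilon = 1/p_0}) and \eqn{1/\log\lambda_1} for the
#' escape transient (\eqn{\varepsilon = p_0}).
#'
#' @param log_epsilon numeric vector of \eqn{\log\varepsilon} values.
#' @param observed_time corresponding observed transient times (pulses).
#' @return List with \code{slope} and \code{intercept} of the regression
#'   of time on \eqn{\log(1/\varepsilon) = -\log\varepsilon}.
#' @export
scaling_slope <- function(log_epsilon, observed_time) {
  if (length(log_epsilon) != length(observed_time))
    stop("'log_epsilon' and 'observed_time' must have equal length")
  ok <- is.finite(log_epsilon) & is.finite(observed_time)
  if (sum(ok) < 3L)
    stop("need at least 3 finite (log_epsilon, observed_time) pairs")
  x <- -log_epsilon[ok]
  co <- stats::coef(stats::lm(observed_time[ok] ~ x))
  list(slope = unname(co[2L]), intercept = unname(co[1L]))
}
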