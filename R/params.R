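#' Nondimensional parameter set for the pulsed consumer-resource map
#'
#' Bundles the six nondimensional parameters that drive the pulse-to-pulse
#' map: per-pulse survival fractions of the consumer (\code{delta_p}) and
#' resource (\code{delta_n}), the consumer conversion intensity
#' (\code{gamma_p}), the scaled attack rate (\code{gamma_n}), the group
#' defense parameter (\code{sigma}, the consumption rate peaks at resource
#' density \eqn{1/\sqrt{\sigma}}), and the per-capita recruit number
#' (\code{R}).
#'
#' Hard invariants (violations are errors): \code{delta_p} and
#' \code{delta_n} strictly inside (0, 1); \code{gamma_p}, \code{gamma_n},
#' \code{sigma}, \code{R} strictly positive; and the self-replenishment
#' condition \code{R > 1 - delta_n}, without which the resource cannot
#' persist even alone.  A soft condition -- carrying capacity above the
#' consumption peak, \eqn{n^* > 1/\sqrt{\sigma}}, which makes group defense
#' relevant below carrying capacity -- triggers a warning only.
#'
#' @param delta_p per-pulse consumer survival fraction, in (0, 1).
#' @param delta_n per-pulse resource survival fraction, in (0, 1).
#' @param gamma_p consumer conversion intensity, > 0.
#' @param gamma_n scaled consumer attack rate, > 0.
#' @param sigma group-defense shape parameter, >= 0 (0 switches group
#'   defense off and the functional response becomes linear in n).
#' @param R per-capita resource recruit number, > 0.
#' @param check_group_defense warn when \eqn{n^* \le 1/\sqrt{\sigma}}
#'   (default \code{TRUE}).
#' @return An object of class \code{cr_params}: a named list with the six
#'   parameters.
#' @seealso [validate_params()] for a non-throwing report,
#'   [nondimensionalize()] to build one from dimensional rates,
#'   [cr_step()] and [cr_simulate()] for the dynamics.
#' @examples
#' p <- cr_params(delta_p = 0.9, delta_n = 0.8, gamma_p = 1,
#'                gamma_n = 1, sigma = 2.67, R = 2)
#' carrying_capacity(p)  # 9
#' @export
cr_params <- function(delta_p, delta_n, gamma_p, gamma_n, sigma, R,
                      check_group_defense = TRUE) {
  par <- list(delta_p = delta_p, delta_n = delta_n, gamma_p = gamma_p,
              gamma_n = gamma_n, sigma = sigma, R = R)
  for (nm in names(par)) {
    v <- par[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm))
  }
  rep <- .param_checks(par)
  bad <- rep[rep$level == "error" & !rep$pass, , drop = FALSE]
  if (nrow(bad) > 0L)
    stop("invalid parameter set: ", paste(bad$message, collapse = "; "))
  if (check_group_defense) {
    wr <- rep[rep$level == "warning" & !rep$pass, , drop = FALSE]
    for (m in wr$message) warning(m, call. = FALSE)
  }
  structure(par, class = "cr_params")
}

#' Dimensional parameters of the impulsive consumer-resource model
#'
#' The eight dimensional rates of the underlying impulsive system:
#' continuous adult mortality punctuated by reproductive pulses at integer
#' times.  Consumers attack resource at rate \code{gamma_N} through a
#' Type IV response peaking at density \eqn{1/\sqrt{\sigma_N}}; consumer
#' recruits are proportional (constant \code{gamma_P}) to resource consumed
#' at the pulse; resource produces \code{R} recruits per capita, which
#' survive consumption with exponentially distributed probability of mean
#' \code{1/gamma_S} and compete with adults at carrying-capacity scale
#' \code{1/beta}.
#'
#' @param d_P,d_N adult consumer / resource mortality rates, > 0.
#' @param gamma_N consumer attack rate, > 0.
#' @param sigma_N group-defense shape parameter, > 0.
#' @param gamma_P consumer recruit conversion constant, > 0.
#' @param gamma_S inverse mean of the offspring consumption-survival
#'   distribution, > 0.
#' @param beta inverse carrying-capacity scale for resource recruits, > 0.
#' @param R per-capita resource recruit number; must exceed
#'   \code{1 - exp(-d_N)} for a self-replenishing resource.
#' @return An object of class \code{cr_dim_params}.
#' @seealso [nondimensionalize()]
#' @export
dim_params <- function(d_P, d_N, gamma_N, sigma_N, gamma_P, gamma_S, beta, R) {
  par <- list(d_P = d_P, d_N = d_N, gamma_N = gamma_N, sigma_N = sigma_N,
              gamma_P = gamma_P, gamma_S = gamma_S, beta = beta, R = R)
  for (nm in names(par)) {
    v <- par[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm))
    if (v <= 0)
      stop(sprintf("'%s' must be strictly positive (got %g)", nm, v))
  }
  if (R <= 1 - exp(-d_N))
    stop(sprintf(
      "self-replenishment requires R > 1 - exp(-d_N): R = %g, 1 - exp(-d_N) = %g",
      R, 1 - exp(-d_N)))
  structure(par, class = "cr_dim_params")
}

#' Convert dimensional rates to the nondimensional parameter set
#'
#' Applies the state scaling \eqn{p = \gamma_S P}, \eqn{n = \beta N} and the
#' parameter mapping \eqn{\delta_p = e^{-d_P}}, \eqn{\delta_n = e^{-d_N}},
#' \eqn{\gamma_p = \gamma_P/\beta}, \eqn{\gamma_n = \gamma_N e^{-d_P}/\gamma_S},
#' \eqn{\sigma = \sigma_N/\beta^2}.  One step of the dimensional
#' discrete-time map, rescaled, equals one step of the nondimensional map
#' under the returned parameters.
#'
#' @param dim a [dim_params()] object.
#' @inheritParams cr_params
#' @return A [cr_params()] object.
#' @export
nondimensionalize <- function(dim, check_group_defense = TRUE) {
  if (!inherits(dim, "cr_dim_params"))
    stop("'dim' must be a cr_dim_params object (see dim_params())")
  cr_params(delta_p = exp(-dim$d_P),
            delta_n = exp(-dim$d_N),
            gamma_p = dim$gamma_P / dim$beta,
            gamma_n = dim$gamma_N * exp(-dim$d_P) / dim$gamma_S,
            sigma   = dim$sigma_N / dim$beta^2,
            R       = dim$R,
            check_group_defense = check_group_defense)
}

# Shared invariant table; returns data.frame(condition, level, pass, message).
.param_checks <- function(par) {
  out <- list()
  add <- function(condition, level, pass, message)
    out[[length(out) + 1L]] <<- data.frame(
      condition = condition, level = level, pass = pass, message = message,
      stringsAsFactors = FALSE)

  in01 <- function(x) is.finite(x) && x > 0 && x < 1
  pos  <- function(x) is.finite(x) && x > 0
  add("delta_p in (0,1)", "error", in01(par$delta_p),
      sprintf("delta_p must lie strictly inside (0, 1), got %g", par$delta_p))
  add("delta_n in (0,1)", "error", in01(par$delta_n),
      sprintf("delta_n must lie strictly inside (0, 1), got %g", par$delta_n))
  for (nm in c("gamma_p", "gamma_n", "R"))
    add(sprintf("%s > 0", nm), "error", pos(par[[nm]]),
        sprintf("%s must be strictly positive, got %g", nm, par[[nm]]))
  # sigma = 0 is the admissible no-group-defense boundary
  add("sigma >= 0", "error", is.finite(par$sigma) && par$sigma >= 0,
      sprintf("sigma must be nonnegative, got %g", par$sigma))

  replenish <- in01(par$delta_n) && pos(par$R) && par$R > 1 - par$delta_n
  add("R > 1 - delta_n (self-replenishing resource)", "error", replenish,
      sprintf("self-replenishment requires R > 1 - delta_n: R = %g, 1 - delta_n = %g",
              par$R, 1 - par$delta_n))

  if (replenish && pos(par$sigma)) {
    nstar <- par$R / (1 - par$delta_n) - 1
    gd <- nstar > 1 / sqrt(par$sigma)
    add("n* > 1/sqrt(sigma) (group defense relevant below carrying capacity)",
        "warning", gd,
        sprintf("carrying capacity n* = %g does not exceed the consumption peak 1/sqrt(sigma) = %g; group defense is irrelevant below carrying capacity",
                nstar, 1 / sqrt(par$sigma)))
  }
  do.call(rbind, out)
}

#' Validate a parameter set without throwing
#'
#' Evaluates every invariant of the nondimensional parameter set and returns
#' a report instead of raising.  Positivity, the (0,1) bounds on the
#' survival fractions and the self-replenishment condition
#' \code{R > 1 - delta_n} are error-level findings; the group-defense
#' relevance condition \eqn{n^* > 1/\sqrt{\sigma}} is warning-level.
#'
#' @param params a [cr_params()] object, or a bare named list with the six
#'   parameter fields (so that invalid candidates can be reported on).
#' @return A data frame of class \code{cr_validation} with columns
#'   \code{condition}, \code{level} (\code{"error"} or \code{"warning"}),
#'   \code{pass} (logical) and \code{message}.
#' @examples
#' validate_params(list(delta_p = 0.9, delta_n = 0.8, gamma_p = 1,
#'                      gamma_n = 1, sigma = 2.67, R = 0.1))
#' @export
validate_params <- function(params) {
  need <- c("delta_p", "delta_n", "gamma_p", "gamma_n", "sigma", "R")
  if (!all(need %in% names(params)))
    stop("params must contain fields: ", paste(need, collapse = ", "))
  rep <- .param_checks(params[need])
  class(rep) <- c("cr_validation", "data.frame")
  rep
}

#' @export
print.cr_params <- function(x, ...) {
  cat("Nondimensional pulsed consumer-resource parameters:\n")
  cat(sprintf("  delta_p = %g, delta_n = %g, gamma_p = %g, gamma_n = %g, sigma = %g, R = %g\n",
              x$delta_p, x$delta_n, x$gamma_p, x$gamma_n, x$sigma, x$R))
  nstar <- x$R / (1 - x$delta_n) - 1
  cat(sprintf("  carrying capacity n* = %g, bifurcation gamma_p* = %g\n",
              nstar, (1 - x$delta_p) * (1 + x$sigma * nstar^2) / nstar))
  invisible(x)
}

#' @export
print.cr_validation <- function(x, ...) {
  status <- ifelse(x$pass, "pass",
                   ifelse(x$level == "error", "FAIL", "warn"))
  cat("Parameter validation report:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %s\n", status[i],
                if (x$pass[i]) x$condition[i] else x$message[i]))
  invisible(x)
}

# Coerce/verify a cr_params argument inside other functions.
.as_params <- function(params) {
  if (inherits(params, "cr_params")) return(params)
  need <- c("delta_p", "delta_n", "gamma_p", "gamma_n", "sigma", "R")
  if (is.list(params) && all(need %in% names(params)))
    return(do.call(cr_params, c(params[need], list(check_group_defense = FALSE))))
  stop("expected a cr_params object")
}
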