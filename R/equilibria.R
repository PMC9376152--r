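# Fixed points of the pulse map and their stability.  Up to four
# biologically relevant equilibria exist: extinction (0,0), the
# resource-only carrying capacity (0, n*), and at most two coexistence
# saddles whose n-coordinates solve (1-delta_p)(1+sigma n^2) = gamma_p n.

#' Resource carrying capacity of the consumer-free map
#'
#' The positive fixed point of the consumer-free resource map,
#' \eqn{n^* = R/(1-\delta_n) - 1}.  Exists (is positive) precisely when the
#' self-replenishment condition \eqn{R > 1 - \delta_n} holds.
#'
#' @param params a [cr_params()] object.
#' @return The carrying capacity \eqn{n^*} (> 0).
#' @export
carrying_capacity <- function(params) {
  params <- .as_params(params)
  if (params$R <= 1 - params$delta_n)
    stop(sprintf(
      "no positive carrying capacity: R = %g <= 1 - delta_n = %g",
      params$R, 1 - params$delta_n))
  params$R / (1 - params$delta_n) - 1
}

#' Transcritical bifurcation value of the consumer conversion intensity
#'
#' The critical conversion intensity
#' \deqn{\gamma_p^* = (1-\delta_p)\,\frac{1+\sigma n^{*2}}{n^*}}
#' at which the resource-only equilibrium \eqn{(0, n^*)} exchanges
#' stability with the upper coexistence saddle: \eqn{(0, n^*)} is stable
#' for \eqn{\gamma_p < \gamma_p^*} and unstable beyond, and exactly at
#' \eqn{\gamma_p^*} the consumer-direction eigenvalue [lambda1()] equals 1.
#'
#' @param params a [cr_params()] object (its own \code{gamma_p} plays no
#'   role in the critical value).
#' @return The bifurcation value \eqn{\gamma_p^*} (> 0).
#' @examples
#' bifurcation_value(cr_params(0.9, 0.8, 1, 1, 2.67, 2))  # about 2.414
#' @export
bifurcation_value <- function(params) {
  params <- .as_params(params)
  nstar <- carrying_capacity(params)
  (1 - params$delta_p) * (1 + params$sigma * nstar^2) / nstar
}

#' Consumer-direction eigenvalue at the resource-only equilibrium
#'
#' The leading Jacobian eigenvalue of the map at \eqn{(0, n^*)},
#' \deqn{\lambda_1 = \delta_p + \gamma_p\,\frac{n^*}{1+\sigma n^{*2}},}
#' i.e. the per-pulse growth factor of a rare consumer invading the
#' resource at carrying capacity.  \eqn{\lambda_1 > 1} iff
#' \eqn{\gamma_p > \gamma_p^*}; its logarithm sets the crawl-by escape
#' clock near \eqn{(0, n^*)}.
#'
#' @param params a [cr_params()] object.
#' @return The eigenvalue \eqn{\lambda_1} (> 0).
#' @export
lambda1 <- function(params) {
  params <- .as_params(params)
  nstar <- carrying_capacity(params)
  params$delta_p + params$gamma_p * nstar / (1 + params$sigma * nstar^2)
}

#' Coexistence equilibria of the pulse map
#'
#' Solves for the pair of coexistence fixed points
#' \eqn{(p^{\vee}, n^{\vee})}, \eqn{(p^{\wedge}, n^{\wedge})}.  The
#' n-coordinates are the roots of the consumer balance
#' \eqn{(1-\delta_p)(1+\sigma n^2) = \gamma_p n},
#' \deqn{n^{\vee\wedge} = \frac{\gamma_p \mp
#'   \sqrt{\gamma_p^2 - 4\sigma(1-\delta_p)^2}}{2\sigma(1-\delta_p)},}
#' and each p-coordinate solves the resource balance
#' \eqn{1 = \delta_n e^{-\gamma_n p/(1+\sigma n^2)} + R e^{-p}/(1+n)},
#' whose right side is strictly decreasing in \eqn{p}, by bracketed
#' root-finding (bracket grown geometrically from 1, Newton-polished to
#' residual near machine precision).
#'
#' Without group defense (\eqn{\sigma = 0}) the quadratic balance
#' degenerates and no coexistence pair exists; likewise when the
#' discriminant is negative or when a root has no positive-p companion.
#'
#' @param params a [cr_params()] object.
#' @return A list of named state vectors \code{c(p, n)}, named
#'   \code{coexistence_low} and \code{coexistence_high} by their
#'   n-coordinate.  Below the bifurcation both points exist; above it the
#'   upper root loses its positive-p companion (the resource balance
#'   already falls short of replacement at \eqn{p = 0}) and is dropped, so
#'   the list may also contain the lower point alone.
#' @export
coexistence_pair <- function(params) {
  params <- .as_params(params)
  if (params$sigma == 0) return(list())
  disc <- params$gamma_p^2 - 4 * params$sigma * (1 - params$delta_p)^2
  if (disc < 0) return(list())
  den <- 2 * params$sigma * (1 - params$delta_p)
  n_roots <- c((params$gamma_p - sqrt(disc)) / den,
               (params$gamma_p + sqrt(disc)) / den)
  out <- list()
  labs <- c("coexistence_low", "coexistence_high")
  for (i in 1:2) {
    n <- n_roots[i]
    if (!is.finite(n) || n <= 0) next
    p <- .solve_coexistence_p(n, params)
    if (!is.null(p)) out[[labs[i]]] <- c(p = p, n = n)
  }
  out
}

# Root of f(p) = delta_n exp(-gamma_n p/(1+sigma n^2)) + R exp(-p)/(1+n) - 1
# on p > 0; f is strictly decreasing, so a sign change brackets the root.
.solve_coexistence_p <- function(n, params) {
  c1 <- params$gamma_n / (1 + params$sigma * n^2)
  f <- function(p) params$delta_n * exp(-c1 * p) +
    params$R * exp(-p) / (1 + n) - 1
  fp <- function(p) -params$delta_n * c1 * exp(-c1 * p) -
    params$R * exp(-p) / (1 + n)
  if (f(0) <= 0) return(NULL)   # RHS already below 1 at p = 0
  hi <- 1
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e6)
      stop(sprintf(
        "coexistence root-finder: no sign change for p in (0, 1e6] at n = %g",
        n))
  }
  p <- stats::uniroot(f, c(0, hi), tol = 1e-14)$root
  for (k in 1:4) p <- p - f(p) / fp(p)   # polish to residual ~ eps
  if (p <= 0) return(NULL)
  p
}

#' Jacobian of the pulse map
#'
#' Analytic matrix of partial derivatives of the one-pulse map at a state,
#' used for stability classification.  At \eqn{(0, n^*)} the matrix is
#' triangular with eigenvalues [lambda1()] and
#' \eqn{\delta_n + R/(1+n^*)^2}; at the origin the eigenvalues are
#' \eqn{\delta_p} and \eqn{\delta_n + R}.
#'
#' @param s state vector \code{c(p, n)}, finite and nonnegative.
#' @param params a [cr_params()] object.
#' @return A 2x2 numeric matrix, rows = (p', n'), columns = (p, n).
#' @export
cr_jacobian <- function(s, params) {
  params <- .as_params(params)
  s <- .check_state(s)
  p <- s[[1L]]; n <- s[[2L]]
  D <- 1 + params$sigma * n^2
  E <- exp(-params$gamma_n * p / D)
  dp_dp <- params$delta_p + params$gamma_p * n / D
  dp_dn <- params$gamma_p * p * (1 - params$sigma * n^2) / D^2
  dn_dp <- -params$delta_n * n * E * params$gamma_n / D -
    params$R * n * exp(-p) / (1 + n)
  dn_dn <- params$delta_n * E *
    (1 + 2 * params$sigma * params$gamma_n * p * n^2 / D^2) +
    params$R * exp(-p) / (1 + n)^2
  matrix(c(dp_dp, dp_dn, dn_dp, dn_dn), nrow = 2L, byrow = TRUE,
         dimnames = list(c("p_next", "n_next"), c("p", "n")))
}

# Classify by eigenvalue moduli; |mod - 1| < tol at any eigenvalue means
# the linearization is inconclusive (nonhyperbolic).
.classify_stability <- function(moduli, tol = 1e-9) {
  if (any(abs(moduli - 1) < tol)) return("nonhyperbolic")
  if (all(moduli < 1)) return("stable")
  if (all(moduli > 1)) return("unstable")
  "saddle"
}

#' Catalog of all fixed points with stability
#'
#' Locates every fixed point of the map with nonnegative coordinates --
#' extinction \eqn{(0,0)}, carrying capacity \eqn{(0, n^*)}, and the
#' coexistence pair when it exists -- and classifies each by the moduli of
#' its Jacobian eigenvalues (all < 1: stable; all > 1: unstable; mixed:
#' saddle; any modulus within \code{tol} of 1: nonhyperbolic).  Also
#' reports the bifurcation value \eqn{\gamma_p^*} and the invasion
#' eigenvalue \eqn{\lambda_1}.
#'
#' @param params a [cr_params()] object.
#' @param tol nonhyperbolicity tolerance on |eigenvalue modulus - 1|.
#' @return An object of class \code{cr_equilibrium_catalog}: a list with
#'   \code{params}, \code{equilibria} (list of entries with
#'   \code{location}, \code{label}, \code{eigenvalues}, \code{moduli},
#'   \code{stability}, \code{in_first_quadrant}), \code{n_star},
#'   \code{gamma_p_star} and \code{lambda_1}.
#' @examples
#' equilibrium_catalog(cr_params(0.9, 0.8, 1, 1, 2.67, 2))
#' @export
equilibrium_catalog <- function(params, tol = 1e-9) {
  params <- .as_params(params)
  nstar <- carrying_capacity(params)
  locs <- list(extinction = c(p = 0, n = 0),
               carrying_capacity = c(p = 0, n = nstar))
  locs <- c(locs, coexistence_pair(params))
  eqs <- lapply(names(locs), function(lab) {
    loc <- locs[[lab]]
    ev <- eigen(cr_jacobian(loc, params), only.values = TRUE)$values
    ev <- as.complex(ev)
    list(location = loc, label = lab, eigenvalues = ev, moduli = Mod(ev),
         stability = .classify_stability(Mod(ev), tol),
         in_first_quadrant = all(loc >= 0))
  })
  names(eqs) <- names(locs)
  structure(list(params = params, equilibria = eqs, n_star = nstar,
                 gamma_p_star = bifurcation_value(params),
                 lambda_1 = lambda1(params)),
            class = "cr_equilibrium_catalog")
}

#' @export
print.cr_equilibrium_catalog <- function(x, ...) {
  cat("Equilibrium catalog of the pulsed consumer-resource map\n")
  cat(sprintf("  n* = %.6g   gamma_p* = %.6g   lambda_1 = %.6g   (gamma_p = %g)\n",
              x$n_star, x$gamma_p_star, x$lambda_1, x$params$gamma_p))
  df <- do.call(rbind, lapply(x$equilibria, function(e)
    data.frame(label = e$label, p = e$location[["p"]], n = e$location[["n"]],
               mod1 = e$moduli[1L], mod2 = e$moduli[2L],
               stability = e$stability)))
  rownames(df) <- NULL
  print(df, digits = 6)
  invisible(x)
}
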