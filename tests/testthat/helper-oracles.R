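# Shared fixtures and independent oracles for the test suite.

# Baseline parameter set used throughout (carrying capacity n* = 9,
# bifurcation value gamma_p* = 2.41411...).
baseline_params <- function(gamma_p = 1) {
  cr_params(delta_p = 0.9, delta_n = 0.8, gamma_p = gamma_p,
            gamma_n = 1, sigma = 2.67, R = 2,
            check_group_defense = FALSE)
}

# One step of the dimensional discrete-time map, written directly from the
# dimensional rate equations: the independent oracle for the
# nondimensionalization commuting square.
dim_step <- function(P, N, d) {
  dP <- exp(-d$d_P); dN <- exp(-d$d_N)
  D <- 1 + d$sigma_N * N^2
  P2 <- dP * P + d$gamma_P * P * N / D
  N2 <- dN * N * exp(-d$gamma_N * dP * P / D) +
    d$R * exp(-d$gamma_S * P) * N / (1 + d$beta * N)
  c(P2, N2)
}

# Random valid dimensional parameter set (all rates positive,
# self-replenishing resource).
random_dim_params <- function() {
  d_N <- runif(1, 0.05, 1.5)
  dim_params(d_P = runif(1, 0.05, 1.5), d_N = d_N,
             gamma_N = runif(1, 0.1, 3), sigma_N = runif(1, 0.05, 5),
             gamma_P = runif(1, 0.1, 3), gamma_S = runif(1, 0.2, 3),
             beta = runif(1, 0.2, 3),
             R = (1 - exp(-d_N)) + runif(1, 0.1, 3))
}

# Random valid nondimensional parameter set.
random_params <- function() {
  delta_n <- runif(1, 0.05, 0.95)
  cr_params(delta_p = runif(1, 0.05, 0.95), delta_n = delta_n,
            gamma_p = runif(1, 0.1, 5), gamma_n = runif(1, 0.1, 5),
            sigma = runif(1, 0.01, 5),
            R = (1 - delta_n) + runif(1, 0.1, 3),
            check_group_defense = FALSE)
}

# relative difference helper
rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.eps)
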