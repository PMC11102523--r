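# Shared fixtures: the benchmark parameter set used throughout the
# package's examples (beta = 0.4, beta1 = 0.1, alpha = 0.03, b = 0.02,
# gamma = 0.002, N = 1e4, S0 = 9900, I0 = 100) and random draws from the
# theory regime alpha > b > gamma.

fig_params <- function(gamma = 0.002) {
  model_params(beta = 0.4, beta1 = 0.1, alpha = 0.03, b = 0.02, gamma = gamma)
}

FIG_N <- 1e4
FIG_S0 <- 9900
FIG_I0 <- 100

# One random parameter set with alpha > b > gamma and beta > beta1 > 0.
draw_theory_params <- function() {
  beta <- stats::runif(1, 0.1, 1)
  beta1 <- beta * stats::runif(1, 0.05, 0.9)
  b <- stats::runif(1, 0.005, 0.05)
  gamma <- b * stats::runif(1, 0.05, 0.9)
  alpha <- b * stats::runif(1, 1.2, 10)
  model_params(beta = beta, beta1 = beta1, alpha = alpha, b = b, gamma = gamma)
}

# Independent root oracle: sign-change bisection of the equilibrium
# quadratic on (0, N), deliberately avoiding the closed form under test.
bisect_I_star <- function(params, N, tol = 1e-12 * N) {
  coefs <- quadratic_coefficients(params, N)
  f <- function(I) coefs$A * I^2 + coefs$B * I + coefs$C
  lo <- 0
  hi <- N
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
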