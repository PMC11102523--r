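test_that("equilibrium quadratic has the closed-form coefficients", {
  co <- quadratic_coefficients(fig_params(), FIG_N)
  expect_equal(co$A, 0.03)
  expect_equal(co$B, 250)
  expect_equal(co$C, -650000)

  # both inhomogeneous sources off: C loses all its mass
  p0 <- model_params(0.4, 0.1, 0.03, 0, 0)
  expect_equal(quadratic_coefficients(p0, FIG_N)$C, 0)

  # beta1 -> beta limit: C tends to -b N^2 continuously
  p1 <- model_params(0.4, 0.4 - 1e-9, 0.03, 0.02, 0.002)
  expect_equal(quadratic_coefficients(p1, FIG_N)$C, -0.02 * FIG_N^2,
               tolerance = 1e-6)

  # C < 0 whenever beta1 < beta (and gamma, b not both zero)
  set.seed(21)
  for (k in 1:50) expect_lt(quadratic_coefficients(draw_theory_params(), FIG_N)$C, 0)
})

test_that("benchmark equilibrium matches the known point and its bounds", {
  eq <- interior_equilibrium(fig_params(), FIG_N)
  expect_equal(eq$I_star, 2080.55, tolerance = 1e-5)
  expect_equal(eq$S_star, 2204.3, tolerance = 1e-4)
  expect_equal(eq$S_lower, 475)
  expect_equal(eq$S_upper, 2900)
  expect_true(eq$S_lower < eq$S_star && eq$S_star < eq$S_upper)
  expect_gt(eq$f_at_N, 0)
  # the fixed point really is a fixed point of the reduced dynamics
  d <- rhs_reduced(eq$S_star, eq$I_star, fig_params(), FIG_N)
  expect_lt(max(abs(d)), 1e-9 * FIG_N)
})

test_that("closed-form root agrees with bisection across the theory regime", {
  set.seed(22)
  for (k in 1:200) {
    p <- draw_theory_params()
    N <- 10^runif(1, 2, 6)
    eq <- interior_equilibrium(p, N)
    expect_lt(abs(eq$I_star - bisect_I_star(p, N)), 1e-8 * N)
    expect_true(eq$I_star > 0 && eq$I_star < N)
    expect_true(eq$S_lower < eq$S_star && eq$S_star < eq$S_upper)
    # the two nullcline branches agree at the root
    expect_equal(viralsir:::s1_of_I(p, N, eq$I_star),
                 viralsir:::s2_of_I(p, N, eq$I_star),
                 tolerance = 1e-8)
  }
})

test_that("equilibrium computation refuses outside the theory regime", {
  p_bad <- model_params(0.4, 0.1, 0.01, 0.02, 0.002)  # alpha < b
  expect_error(interior_equilibrium(p_bad, FIG_N), "alpha > b > gamma")
  p_bad2 <- model_params(0.4, 0.1, 0.03, 0.02, 0.03)  # gamma > b
  expect_error(interior_equilibrium(p_bad2, FIG_N), "alpha > b > gamma")
  expect_error(quadratic_coefficients(fig_params(), -10), "positive")
})

test_that("stability certificate: coefficients, eigenvalues and verdict", {
  p <- fig_params()
  eq <- interior_equilibrium(p, FIG_N)
  st <- stability_report(p, FIG_N, eq)
  # hand-substituted characteristic coefficients at the benchmark point
  expect_equal(st$B_bar, 0.09255, tolerance = 1e-4)
  expect_equal(st$C_bar, 0.0025822, tolerance = 1e-4)
  expect_true(st$stable)
  # cross-check the characteristic roots against a generic eigensolver
  lam <- eigen(st$jacobian, only.values = TRUE)$values
  expect_equal(sort(Re(lam)), sort(Re(st$eigenvalues)), tolerance = 1e-10)
  expect_equal(sort(abs(Im(lam))), sort(abs(Im(st$eigenvalues))), tolerance = 1e-10)
})

test_that("trace/determinant identities and positivity hold across the regime", {
  set.seed(23)
  for (k in 1:100) {
    p <- draw_theory_params()
    N <- 10^runif(1, 2, 6)
    st <- stability_report(p, N)
    expect_equal(sum(diag(st$jacobian)), -st$B_bar, tolerance = 1e-10)
    expect_equal(det(st$jacobian), st$C_bar, tolerance = 1e-10)
    expect_gt(st$B_bar, 0)
    expect_gt(st$C_bar, 0)
    expect_true(st$stable)
  }
})

test_that("reduced dynamics converge to the equilibrium from random interior starts", {
  set.seed(24)
  for (k in 1:10) {
    p <- draw_theory_params()
    N <- 1e4
    eq <- interior_equilibrium(p, N)
    st <- stability_report(p, N, eq)
    horizon <- max(300, 30 / abs(max(Re(st$eigenvalues))))
    for (j in 1:3) {
      S0 <- runif(1, 0.05, 1.5) * N
      I0 <- runif(1, 0.01, 1) * N
      traj <- simulate_sir(p, S0, I0, t_end = horizon, dt = horizon / 50, N = N)
      n <- nrow(traj)
      expect_lt(abs(traj$S[n] - eq$S_star), 1e-4 * N)
      expect_lt(abs(traj$I[n] - eq$I_star), 1e-4 * N)
    }
  }
})

test_that("gamma sweep: S* falls, I* rises, their sum is non-monotone", {
  p <- fig_params()
  grid <- seq(0, 0.019, length.out = 20)
  tab <- equilibrium_vs_gamma(p, FIG_N, grid)
  expect_true(all(tab$in_regime))
  expect_true(all(diff(tab$S_star) < 0))
  expect_true(all(diff(tab$I_star) > 0))
  dsum <- diff(tab$S_plus_I)
  expect_true(any(dsum > 0) && any(dsum < 0))

  # gamma = 0 reduces the quadratic to its advertising-free form
  co0 <- quadratic_coefficients(model_params(0.4, 0.1, 0.03, 0.02, 0), FIG_N)
  I0_root <- (-co0$B + sqrt(co0$B^2 - 4 * co0$A * co0$C)) / (2 * co0$A)
  expect_equal(tab$I_star[1], I0_root, tolerance = 1e-12)

  # grid points violating b > gamma are flagged, not extrapolated
  tab2 <- equilibrium_vs_gamma(p, FIG_N, c(0.001, 0.05))
  expect_false(tab2$in_regime[2])
  expect_true(is.na(tab2$S_star[2]))
})
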