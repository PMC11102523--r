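#' Quadratic whose positive root is the sharer equilibrium
#'
#' Eliminating S from the steady-state conditions of the reduced system
#' leaves a quadratic in the sharer count,
#' `f(I) = A I^2 + B I + C` with
#' `A = alpha`, `B = (alpha - (beta1/beta) b) N` and
#' `C = -(1 - beta1/beta) gamma N^2 - (beta1/beta) b N^2`.
#' Since `beta1 < beta` forces `C < 0` (and `A > 0`), `f` always has
#' exactly one positive root.
#'
#' @param params a [model_params()] object with `beta > 0`.
#' @param N reference population size, `> 0`.
#' @return List of class `quadratic_coefficients` with fields `A`, `B`, `C`.
#' @examples
#' p <- model_params(0.4, 0.1, 0.03, 0.02, 0.002)
#' quadratic_coefficients(p, 1e4)  # A = 0.03, B = 250, C = -650000
#' @export
quadratic_coefficients <- function(params, N) {
  stopifnot_params(params)
  if (params$beta <= 0) stop("'beta' must be positive", call. = FALSE)
  if (N <= 0) stop("'N' must be positive", call. = FALSE)
  ratio <- params$beta1 / params$beta
  structure(
    list(A = params$alpha,
         B = (params$alpha - ratio * params$b) * N,
         C = -(1 - ratio) * params$gamma * N^2 - ratio * params$b * N^2),
    class = "quadratic_coefficients"
  )
}

eval_quadratic <- function(coefs, I) {
  coefs$A * I^2 + coefs$B * I + coefs$C
}

# S as a function of I on each nullcline: S1 from the S-equation,
# S2 from the I-equation. They intersect at the equilibrium.
s1_of_I <- function(params, N, I) {
  (N / (params$beta * I)) * (params$b * N - params$gamma * N^2 / (N + I))
}

s2_of_I <- function(params, N, I) {
  (N / (params$beta1 * I)) * (params$alpha * I - params$gamma * N^2 / (N + I))
}

#' Interior equilibrium of the reduced system
#'
#' Computes the unique positive fixed point `(S*, I*)` of the reduced
#' (S, I) dynamics: `I*` is the positive root
#' `(-B + sqrt(B^2 - 4AC)) / (2A)` of the quadratic from
#' [quadratic_coefficients()], and `S*` follows from the susceptible
#' nullcline `S1(I)`. The theory guarantees, in the regime
#' `alpha > b > gamma` (with `beta > beta1`), that `0 < I* < N` and that
#' `S*` lies between `S_lower = (b - gamma/2) N / beta` and
#' `S_upper = (alpha - gamma/2) N / beta1`. Outside the regime the
#' function refuses: the theorems prove nothing there and a silently
#' returned root could be spurious.
#'
#' @param params a [model_params()] object with `theory_regime = TRUE`.
#' @param N reference population size, `> 0`.
#' @return An `equilibrium_report`: list with `S_star`, `I_star`,
#'   `S_lower`, `S_upper`, `f_at_N` (the quadratic evaluated at `I = N`,
#'   positive in the regime), the `coefficients`, and `N`.
#' @examples
#' p <- model_params(0.4, 0.1, 0.03, 0.02, 0.002)
#' interior_equilibrium(p, 1e4)  # I* ~ 2080.6, S* ~ 2204.3
#' @export
interior_equilibrium <- function(params, N) {
  require_theory_regime(params)
  if (params$beta1 <= 0) {
    stop("'beta1' must be positive for the interior equilibrium", call. = FALSE)
  }
  coefs <- quadratic_coefficients(params, N)
  disc <- coefs$B^2 - 4 * coefs$A * coefs$C
  # C < 0 guarantees a positive discriminant; a failure here means broken inputs
  stopifnot(disc > 0)
  I_star <- (-coefs$B + sqrt(disc)) / (2 * coefs$A)
  S_star <- s1_of_I(params, N, I_star)
  structure(
    list(S_star = S_star,
         I_star = I_star,
         S_lower = (params$b - params$gamma / 2) * N / params$beta,
         S_upper = (params$alpha - params$gamma / 2) * N / params$beta1,
         f_at_N = eval_quadratic(coefs, N),
         coefficients = coefs,
         N = N,
         params = params),
    class = "equilibrium_report"
  )
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("Interior equilibrium of the reduced (S, I) system\n")
  cat(sprintf("  S* = %.6g, I* = %.6g  (N = %g)\n", x$S_star, x$I_star, x$N))
  cat(sprintf("  bounds: S_lower = %.6g < S* < S_upper = %.6g\n",
              x$S_lower, x$S_upper))
  cat(sprintf("  quadratic: A = %.6g, B = %.6g, C = %.6g, f(N) = %.6g\n",
              x$coefficients$A, x$coefficients$B, x$coefficients$C, x$f_at_N))
  invisible(x)
}

#' Local-stability certificate at the interior equilibrium
#'
#' Evaluates the Jacobian of the reduced system at `(S*, I*)`, the
#' characteristic-polynomial coefficients
#' `Bbar = beta I*/N + alpha + gamma N^2/(N+I*)^2 - beta1 S*/N` and
#' `Cbar = (beta-beta1) gamma N I*/(N+I*)^2 + beta alpha I*/N`
#' (so the eigenvalues solve `lambda^2 + Bbar lambda + Cbar = 0`), and a
#' stability verdict. In the theory regime both coefficients are
#' positive, both eigenvalue real parts are negative, and the equilibrium
#' is in fact globally asymptotically stable on the open positive
#' quadrant.
#'
#' @param params a [model_params()] object.
#' @param N reference population size.
#' @param eq optionally, a precomputed [interior_equilibrium()] report.
#' @return A `stability_report`: list with the 2x2 `jacobian`, `B_bar`,
#'   `C_bar`, complex `eigenvalues`, and logical `stable`.
#' @export
stability_report <- function(params, N, eq = NULL) {
  if (is.null(eq)) eq <- interior_equilibrium(params, N)
  S <- eq$S_star
  I <- eq$I_star
  ad_slope <- params$gamma * N^2 / (N + I)^2  # -d/dI of the advertising load
  J <- matrix(c(-params$beta * I / N,
                params$beta1 * I / N,
                -params$beta * S / N + ad_slope,
                params$beta1 * S / N - ad_slope - params$alpha),
              nrow = 2, ncol = 2,
              dimnames = list(c("dS", "dI"), c("S", "I")))
  B_bar <- params$beta * I / N + params$alpha + ad_slope - params$beta1 * S / N
  C_bar <- (params$beta - params$beta1) * params$gamma * N * I / (N + I)^2 +
    params$beta * params$alpha * I / N
  disc <- as.complex(B_bar^2 - 4 * C_bar)
  eigenvalues <- c((-B_bar + sqrt(disc)) / 2, (-B_bar - sqrt(disc)) / 2)
  structure(
    list(jacobian = J, B_bar = B_bar, C_bar = C_bar,
         eigenvalues = eigenvalues,
         stable = all(Re(eigenvalues) < 0)),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability at the interior equilibrium\n")
  cat(sprintf("  B_bar = %.6g, C_bar = %.6g\n", x$B_bar, x$C_bar))
  cat(sprintf("  eigenvalues: %s, %s\n",
              format(x$eigenvalues[1L], digits = 6),
              format(x$eigenvalues[2L], digits = 6)))
  cat(sprintf("  locally stable: %s\n", if (x$stable) "yes" else "no"))
  invisible(x)
}

#' Equilibrium as a function of the advertising rate
#'
#' Sweeps `gamma` over a grid, recomputing the interior equilibrium at
#' each value while the other rates stay fixed. Heavier advertising
#' drives the susceptible pool down and the sharer pool up monotonically,
#' but their sum `S* + I*` responds non-monotonically, so the advertising
#' rate that maximises eventual viewership is an interior value. Grid
#' points that leave the theory regime (`gamma >= b`) are flagged and
#' their equilibrium columns set to `NA` rather than extrapolated.
#'
#' @param params a [model_params()] object (its `gamma` is ignored).
#' @param N reference population size.
#' @param gamma_grid numeric vector of advertising rates, `>= 0`.
#' @return Data frame with columns `gamma`, `S_star`, `I_star`,
#'   `S_plus_I`, `in_regime`.
#' @export
equilibrium_vs_gamma <- function(params, N, gamma_grid) {
  stopifnot_params(params)
  rows <- lapply(gamma_grid, function(g) {
    p <- model_params(params$beta, params$beta1, params$alpha, params$b, g)
    if (!p$theory_regime) {
      return(data.frame(gamma = g, S_star = NA_real_, I_star = NA_real_,
                        S_plus_I = NA_real_, in_regime = FALSE))
    }
    eq <- interior_equilibrium(p, N)
    data.frame(gamma = g, S_star = eq$S_star, I_star = eq$I_star,
               S_plus_I = eq$S_star + eq$I_star, in_regime = TRUE)
  })
  do.call(rbind, rows)
}
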