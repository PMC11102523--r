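#' Advertising forcing term
#'
#' The instantaneous rate (individuals/day) at which advertising converts
#' susceptibles into active sharers: `gamma * N^2 / (N + I)`. It equals
#' `gamma * N` when no one is sharing, decreases strictly in the number of
#' sharers `I`, and tends to 0 as `I` grows: advertising spend is assumed
#' highest when the video has no organic momentum and is withdrawn once
#' sharers sustain the spread on their own.
#'
#' @param gamma advertising rate (per day), `>= 0`.
#' @param N reference population size, `> 0`.
#' @param I current number of active sharers, `>= 0`. Vectorised.
#' @return Recruitment rate(s), individuals per day.
#' @examples
#' advertising_load(0.002, 1e4, 0)     # gamma * N = 20
#' advertising_load(0.002, 1e4, 1e4)   # halved: 10
#' @export
advertising_load <- function(gamma, N, I) {
  if (!is.finite(N) || N <= 0) stop("'N' must be positive", call. = FALSE)
  if (!is.finite(gamma) || gamma < 0) stop("'gamma' must be nonnegative", call. = FALSE)
  if (any(!is.finite(I)) || any(I < 0)) stop("'I' must be nonnegative", call. = FALSE)
  gamma * N^2 / (N + I)
}

#' Right-hand side of the full three-compartment system
#'
#' Derivatives of (S, I, R) under the sharing-plus-advertising model:
#' \deqn{S' = -\beta I S / N - \gamma N^2/(I+N) + bN}
#' \deqn{I' = \beta_1 I S / N + \gamma N^2/(I+N) - \alpha I}
#' \deqn{R' = (\beta-\beta_1) I S / N + \alpha I}
#' The components sum to `b*N` exactly: total head count grows linearly
#' through new-user inflow while contacts and advertising only move
#' individuals between compartments.
#'
#' @param S,I,R compartment sizes (individuals, `>= 0`).
#' @param params a [model_params()] object.
#' @param N reference population size (held constant; conventionally
#'   `S0 + I0 + R0`).
#' @return Named numeric vector `c(dS, dI, dR)`.
#' @export
rhs_full <- function(S, I, R, params, N) {
  stopifnot_params(params)
  contact <- params$beta * I * S / N
  # direct formula rather than advertising_load(): adaptive solvers probe
  # trial states with I a hair below zero, which the strict user-facing
  # validator would reject
  ad <- params$gamma * N^2 / (N + I)
  dS <- -contact - ad + params$b * N
  dI <- params$beta1 * I * S / N + ad - params$alpha * I
  dR <- (params$beta - params$beta1) * I * S / N + params$alpha * I
  c(dS = dS, dI = dI, dR = dR)
}

#' Right-hand side of the reduced two-dimensional system
#'
#' With `N` constant, `R` follows from the linear first integral
#' `S + I + R = N0 + b*N*t`, so the dynamics close on (S, I). These are
#' the first two components of [rhs_full()]; the equilibrium analysis and
#' calibration work on this reduced system.
#'
#' @inheritParams rhs_full
#' @return Named numeric vector `c(dS, dI)`.
#' @export
rhs_reduced <- function(S, I, params, N) {
  full <- rhs_full(S, I, 0, params, N)
  full[c("dS", "dI")]
}

#' Right-hand side of the fraction-form system
#'
#' Dynamics of the compartment fractions `s = S/N`, `i = I/N`, `r = R/N`
#' when the total population `N(t)` itself grows, obtained by substituting
#' the fractions into the full system. The components sum to
#' `b * (1 - s - i - r)`, so the simplex `s + i + r = 1` is invariant.
#' Only the right-hand side is provided: the fixed points of this system
#' solve a cubic and no equilibrium or stability support is offered.
#'
#' @param s,i,r compartment fractions (dimensionless, `>= 0`).
#' @param params a [model_params()] object.
#' @return Named numeric vector `c(ds, di, dr)`.
#' @export
rhs_fractions <- function(s, i, r, params) {
  stopifnot_params(params)
  ad <- params$gamma / (i + 1)
  ds <- -params$beta * i * s - ad + params$b - params$b * s
  di <- params$beta1 * i * s + ad - params$alpha * i - params$b * i
  dr <- (params$beta - params$beta1) * i * s + params$alpha * i - r * params$b
  c(ds = ds, di = di, dr = dr)
}

#' Integrate the full model
#'
#' Solves the three-compartment system with an adaptive Runge-Kutta 4(5)
#' scheme (Dormand-Prince, via \pkg{deSolve}), holding the reference
#' population at `N = S0 + I0 + R0`, and samples the solution on a regular
#' output grid. Tolerances default to `rtol = 1e-8` and
#' `atol = 1e-10 * N0`, tight enough that the linear first integral
#' `S + I + R - N0 - b*N*t` stays below `1e-6 * N0` on fixture-scale runs.
#'
#' @param params a [model_params()] object.
#' @param S0,I0,R0 initial compartment sizes (individuals, `>= 0`).
#' @param t_end integration horizon (days, `> 0`).
#' @param dt output grid spacing (days); the integrator steps adaptively
#'   regardless.
#' @param N reference population size entering the rates; defaults to
#'   `S0 + I0 + R0` (the model's convention). Set explicitly when the
#'   start is not a full-population split, e.g. when probing convergence
#'   toward an equilibrium computed at a given `N`.
#' @param rtol,atol relative / absolute integrator tolerances; `atol`
#'   defaults to `1e-10 * N`.
#' @return A `sir_trajectory`: a data frame with columns `t`, `S`, `I`,
#'   `R` and attributes `params` and `N`.
#' @examples
#' p <- model_params(0.4, 0.1, 0.03, 0.02, 0.002)
#' traj <- simulate_sir(p, S0 = 9900, I0 = 100, t_end = 100)
#' head(traj)
#' @export
simulate_sir <- function(params, S0, I0, R0 = 0, t_end, dt = 0.1,
                         N = NULL, rtol = 1e-8, atol = NULL) {
  stopifnot_params(params)
  if (any(c(S0, I0, R0) < 0)) stop("initial compartments must be nonnegative", call. = FALSE)
  if (!is.finite(t_end) || t_end <= 0) stop("'t_end' must be positive", call. = FALSE)
  if (is.null(N)) N <- S0 + I0 + R0
  if (N <= 0) stop("reference population must be positive", call. = FALSE)
  if (is.null(atol)) atol <- 1e-10 * N

  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  deriv <- function(t, y, parms) {
    list(rhs_full(y[1L], y[2L], y[3L], params, N))
  }
  sol <- deSolve::ode(y = c(S = S0, I = I0, R = R0), times = times,
                      func = deriv, parms = NULL, method = "ode45",
                      rtol = rtol, atol = atol)
  if (nrow(sol) < length(times) || any(!is.finite(sol))) {
    istate <- attr(sol, "istate")
    stop("ODE integration failed (",
         nrow(sol), "/", length(times), " grid points reached",
         if (!is.null(istate)) paste0(", istate = ", istate[1L]) else "",
         "); consider a smaller dt or looser tolerances", call. = FALSE)
  }
  traj <- as.data.frame(unclass(sol))
  names(traj)[1L] <- "t"
  structure(traj, params = params, N = N,
            class = c("sir_trajectory", "data.frame"))
}

#' Integrate the fraction-form system
#'
#' Convenience wrapper solving the fraction dynamics with the same
#' adaptive scheme as [simulate_sir()]. No equilibrium theory is attached.
#'
#' @param params a [model_params()] object.
#' @param s0,i0,r0 initial fractions.
#' @param t_end horizon (days).
#' @param dt output grid spacing (days).
#' @return Data frame with columns `t`, `s`, `i`, `r`.
#' @export
simulate_fractions <- function(params, s0, i0, r0 = 0, t_end, dt = 0.1) {
  stopifnot_params(params)
  times <- seq(0, t_end, by = dt)
  deriv <- function(t, y, parms) list(rhs_fractions(y[1L], y[2L], y[3L], params))
  sol <- deSolve::ode(y = c(s = s0, i = i0, r = r0), times = times,
                      func = deriv, parms = NULL, method = "ode45",
                      rtol = 1e-8, atol = 1e-12)
  out <- as.data.frame(unclass(sol))
  names(out)[1L] <- "t"
  out
}

#' Conservation residual of a trajectory
#'
#' Maximum absolute deviation of `S + I + R` from the linear first
#' integral `N0 + b*N*t` along a trajectory; a direct check on integrator
#' accuracy.
#'
#' @param traj a `sir_trajectory` from [simulate_sir()].
#' @return Scalar, individuals.
#' @export
conservation_residual <- function(traj) {
  params <- attr(traj, "params")
  N <- attr(traj, "N")
  n0 <- traj$S[1L] + traj$I[1L] + traj$R[1L]
  max(abs(traj$S + traj$I + traj$R - n0 - params$b * N * traj$t))
}
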