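#' Daily view-count series with cumulative totals
#'
#' Wraps a vector of daily view counts `g_i` (day 0 first) together with
#' its exact prefix sums, the cumulative views `<R>_i = sum_{k<=i} g_k`
#' that the calibration compares against the model's recovered class.
#'
#' @param daily nonnegative daily view counts, one per day starting at
#'   day 0.
#' @param days optional integer day indices (defaults to `0:(n-1)`).
#' @return A `view_series`: data frame with columns `day`, `daily`,
#'   `cumulative`.
#' @examples
#' view_series(c(1, 2, 3))$cumulative  # 1 3 6
#' @export
view_series <- function(daily, days = seq_along(daily) - 1L) {
  if (any(!is.finite(daily)) || any(daily < 0)) {
    stop("daily view counts must be nonnegative", call. = FALSE)
  }
  if (length(days) != length(daily)) {
    stop("'days' and 'daily' must have equal length", call. = FALSE)
  }
  if (any(diff(days) <= 0)) {
    stop("'days' must be strictly increasing", call. = FALSE)
  }
  daily <- as.numeric(daily)
  structure(
    data.frame(day = as.integer(days), daily = daily, cumulative = cumsum(daily)),
    class = c("view_series", "data.frame")
  )
}

#' @rdname view_series
#' @export
cumulative_from_daily <- function(daily) view_series(daily)

#' Model-implied daily views
#'
#' First differences `G(i) = R(i) - R(i-1)` of the recovered class along
#' a trajectory sampled at integer days; the model-side counterpart of
#' observed daily view counts.
#'
#' @param traj a `sir_trajectory` whose grid contains the integer days.
#' @return Data frame with columns `day` (from 1) and `G`.
#' @export
model_daily_views <- function(traj) {
  if (!inherits(traj, "sir_trajectory")) {
    stop("'traj' must be a sir_trajectory", call. = FALSE)
  }
  days <- seq(0, floor(max(traj$t)))
  idx <- match(days, traj$t)
  if (any(is.na(idx))) {
    R_days <- stats::approx(traj$t, traj$R, xout = days)$y
  } else {
    R_days <- traj$R[idx]
  }
  data.frame(day = days[-1L], G = diff(R_days))
}

#' Calibration configuration
#'
#' Settings for fitting the model to a cumulative view series. By
#' default the initial audience is `S0 = 2e9` (the platform's active-user
#' scale) with `I0 = 100` seeded sharers, and all five rates are free;
#' restrict `free_params` to `c("beta", "beta1", "alpha", "gamma")` for
#' the strict four-parameter fit. Parameters not in `free_params` stay
#' fixed at their `theta0` values.
#'
#' @param theta0 named numeric vector of starting values for all five
#'   rates (`beta`, `beta1`, `alpha`, `gamma`, `b`), all positive with
#'   `beta1 < beta`.
#' @param free_params character vector naming the rates to optimise.
#' @param S0,I0 initial susceptible / sharer counts; `R0` is 0.
#' @param max_iter Nelder-Mead iteration cap per restart.
#' @param tolerance relative convergence tolerance of the simplex.
#' @param n_restarts number of jittered restarts (the simplex search is
#'   initialisation-sensitive).
#' @param seed integer seed controlling the restart jitter.
#' @return A `fit_config` list.
#' @export
fit_config <- function(theta0,
                       free_params = c("beta", "beta1", "alpha", "gamma", "b"),
                       S0 = 2e9, I0 = 100,
                       max_iter = 2000L, tolerance = 1e-12,
                       n_restarts = 5L, seed = 1L) {
  all_names <- c("beta", "beta1", "alpha", "gamma", "b")
  if (!all(all_names %in% names(theta0))) {
    stop("'theta0' must name all of: ", paste(all_names, collapse = ", "),
         call. = FALSE)
  }
  if (!all(free_params %in% all_names)) {
    stop("unknown entries in 'free_params'", call. = FALSE)
  }
  if (any(theta0[all_names] <= 0) || theta0["beta1"] >= theta0["beta"]) {
    stop("'theta0' rates must be positive with beta1 < beta", call. = FALSE)
  }
  if (S0 <= 0 || I0 <= 0) stop("'S0' and 'I0' must be positive", call. = FALSE)
  structure(
    list(theta0 = theta0[all_names], free_params = free_params,
         S0 = S0, I0 = I0, max_iter = as.integer(max_iter),
         tolerance = tolerance, n_restarts = as.integer(n_restarts),
         seed = as.integer(seed)),
    class = "fit_config"
  )
}

# Recovered-class path at integer days 0..t_max, on the lsoda stack: the
# cost is evaluated thousands of times inside the simplex search, where
# the heavier Runge-Kutta driver of simulate_sir() would dominate runtime.
# Absolute tolerance 1e-4 individuals is far below any view count of
# interest.
integrate_recovered <- function(params, S0, I0, t_max) {
  N <- S0 + I0
  deriv <- function(t, y, parms) list(rhs_full(y[1L], y[2L], y[3L], params, N))
  sol <- deSolve::ode(c(S = S0, I = I0, R = 0), 0:t_max, deriv, NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-4)
  if (nrow(sol) < t_max + 1L || any(!is.finite(sol[, "R"]))) {
    stop("ODE integration failed inside the cost function", call. = FALSE)
  }
  unname(sol[, "R"])
}

theta_to_params <- function(theta) {
  model_params(beta = theta[["beta"]], beta1 = theta[["beta1"]],
               alpha = theta[["alpha"]], b = theta[["b"]],
               gamma = theta[["gamma"]])
}

# Unconstrained search coordinates: log for (beta, alpha, gamma, b) keeps
# them positive; beta1 is carried as logit(beta1/beta) so 0 < beta1 < beta
# holds for any real value.
theta_to_u <- function(theta, free) {
  u <- numeric(0)
  for (nm in free) {
    u <- c(u, if (nm == "beta1") {
      stats::qlogis(min(max(theta[["beta1"]] / theta[["beta"]], 1e-12), 1 - 1e-12))
    } else {
      log(theta[[nm]])
    })
  }
  names(u) <- free
  u
}

u_to_theta <- function(u, theta0, free) {
  theta <- theta0
  for (nm in setdiff(free, "beta1")) theta[[nm]] <- exp(u[[nm]])
  if ("beta1" %in% free) {
    theta[["beta1"]] <- theta[["beta"]] * stats::plogis(u[["beta1"]])
  }
  theta
}

#' Normalised least-squares cost of a parameter set
#'
#' The calibration objective: the model is integrated from
#' `(S0, I0, R0 = 0)` with `N = S0 + I0`, its recovered class is read off
#' at the observation days, and
#' \deqn{Er = \frac{\sum_i [\langle R\rangle_i - R(t_i, \theta)]^2}
#'                 {(\max_i \langle R\rangle_i)^2 \; t_{max}}}
#' where `t_max` is the largest day index. The normalisation makes `Er`
#' invariant to rescaling the series (and model) by a common factor, so
#' fits to videos of very different popularity are comparable.
#'
#' @param series a [view_series()] with a positive maximum cumulative
#'   count and `t_max > 0`.
#' @param params a [model_params()] object.
#' @param config a [fit_config()] (supplies `S0`, `I0`).
#' @return Scalar cost, `>= 0`.
#' @export
cost_er <- function(series, params, config) {
  if (!inherits(series, "view_series")) {
    stop("'series' must be a view_series", call. = FALSE)
  }
  stopifnot_params(params)
  max_R <- max(series$cumulative)
  t_max <- max(series$day)
  if (max_R <= 0) {
    stop("all-zero view series: the normalisation by max cumulative views is undefined",
         call. = FALSE)
  }
  if (t_max <= 0) {
    stop("'series' must span at least one day (t_max > 0)", call. = FALSE)
  }
  R_path <- integrate_recovered(params, config$S0, config$I0, t_max)
  R_model <- R_path[series$day + 1L]
  sum((series$cumulative - R_model)^2) / (max_R^2 * t_max)
}

#' Fit the model to a cumulative view series
#'
#' Minimises [cost_er()] over the free parameters with Nelder-Mead
#' simplex search (`stats::optim`). The search runs in unconstrained
#' coordinates - logarithms for `beta`, `alpha`, `gamma`, `b` and a
#' logistic map for the ratio `beta1/beta` - so nonnegativity and
#' `beta1 < beta` hold by construction. Because the simplex is sensitive
#' to its starting point, `n_restarts` searches are run from
#' multiplicatively jittered starts (seeded, hence reproducible) and the
#' best is kept; restarts stop early once the cost falls below 1e-12.
#'
#' @param series a [view_series()].
#' @param config a [fit_config()].
#' @return A `fit_result`: list with `params` (fitted [model_params()]),
#'   `theta_hat` (named vector incl. the `beta1/beta` ratio), `er`,
#'   `converged`, `iterations`, `restart_costs`.
#' @export
fit_views <- function(series, config) {
  if (!inherits(config, "fit_config")) {
    stop("'config' must come from fit_config()", call. = FALSE)
  }
  free <- config$free_params
  objective <- function(u) {
    names(u) <- free
    theta <- u_to_theta(u, config$theta0, free)
    val <- tryCatch(cost_er(series, theta_to_params(theta), config),
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1e12 else val
  }

  u0 <- theta_to_u(config$theta0, free)
  set.seed(config$seed)
  starts <- vector("list", config$n_restarts)
  starts[[1L]] <- u0
  if (config$n_restarts > 1L) {
    for (k in 2:config$n_restarts) {
      starts[[k]] <- u0 + stats::rnorm(length(u0), sd = 0.3)
    }
  }

  best <- NULL
  restart_costs <- numeric(0)
  iters <- 0L
  stalled <- 0L
  for (st in starts) {
    opt <- stats::optim(st, objective, method = "Nelder-Mead",
                        control = list(maxit = config$max_iter,
                                       reltol = config$tolerance))
    restart_costs <- c(restart_costs, opt$value)
    iters <- iters + opt$counts[["function"]]
    improved <- is.null(best) || opt$value < 0.99 * best$value
    if (is.null(best) || opt$value < best$value) best <- opt
    # Stop early once the search is clearly done: either an essentially
    # perfect fit, or two consecutive restarts landing in the same basin.
    if (best$value < 1e-12) break
    stalled <- if (improved) 0L else stalled + 1L
    if (stalled >= 2L) break
  }

  u_hat <- best$par
  names(u_hat) <- free
  theta_hat <- u_to_theta(u_hat, config$theta0, free)
  params_hat <- theta_to_params(theta_hat)
  structure(
    list(params = params_hat,
         theta_hat = c(theta_hat,
                       ratio = theta_hat[["beta1"]] / theta_hat[["beta"]]),
         er = best$value,
         converged = best$convergence == 0L,
         iterations = iters,
         restart_costs = restart_costs,
         config = config),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Model fit to cumulative views (Nelder-Mead)\n")
  th <- x$theta_hat
  cat(sprintf("  beta = %.6g, beta1 = %.6g (beta1/beta = %.4f)\n",
              th[["beta"]], th[["beta1"]], th[["ratio"]]))
  cat(sprintf("  alpha = %.6g, gamma = %.6g, b = %.6g\n",
              th[["alpha"]], th[["gamma"]], th[["b"]]))
  cat(sprintf("  Er = %.6g  (converged: %s, %d cost evaluations over %d restart(s))\n",
              x$er, if (x$converged) "yes" else "no",
              x$iterations, length(x$restart_costs)))
  invisible(x)
}
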