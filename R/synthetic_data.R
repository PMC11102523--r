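#' Configuration for synthetic view-count series
#'
#' Describes a synthetic video: true model parameters, initial audience,
#' horizon, and the observation-noise level. The generator integrates
#' the model, forms the noiseless daily views `G(i) = R(i) - R(i-1)`, and
#' perturbs each day multiplicatively. Real view-count data are observed
#' with day-to-day stochasticity the deterministic model does not carry;
#' since daily views span orders of magnitude over a video's life,
#' the default noise is mean-preserving log-normal:
#' `g_i = G(i) * exp(eps_i - sigma^2/2)` with `eps_i ~ N(0, sigma^2)`, so
#' `E[g_i] = G(i)` exactly. A Poisson alternative (`noise = "poisson"`,
#' `g_i ~ Pois(G(i))`) is available for count-like small-scale series.
#'
#' @param true_params a [model_params()] object.
#' @param S0,I0 initial susceptible / sharer counts. The default audience
#'   (1e6) is deliberately far below platform scale so that recovery
#'   experiments run in seconds.
#' @param n_days series length (`>= 2`); days run 0..`n_days`, day 0
#'   having zero views (the video launches with `R(0) = 0`).
#' @param noise_sigma log-scale standard deviation of the daily noise
#'   (`>= 0`; 0 reproduces the model exactly).
#' @param noise `"lognormal"` or `"poisson"`.
#' @param seed integer RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(true_params, S0 = 1e6, I0 = 100, n_days = 200L,
                         noise_sigma = 0, noise = c("lognormal", "poisson"),
                         seed = 1L) {
  stopifnot_params(true_params)
  noise <- match.arg(noise)
  if (n_days < 2) stop("'n_days' must be at least 2", call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be nonnegative", call. = FALSE)
  structure(
    list(true_params = true_params, S0 = S0, I0 = I0,
         n_days = as.integer(n_days), noise_sigma = noise_sigma,
         noise = noise, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic daily view series
#'
#' Integrates the model under the configured true parameters and emits a
#' noisy daily view series alongside the noiseless truth, giving the
#' calibration a ground-truth target with the statistical structure it
#' assumes. Deterministic given the seed.
#'
#' @param config a [synth_config()].
#' @return List with `series` (noisy [view_series()]), `truth` (noiseless
#'   [view_series()]), `trajectory` (the underlying `sir_trajectory`) and
#'   `config`.
#' @examples
#' p <- model_params(0.4, 0.1, 0.03, 0.02, 0.002)
#' sim <- generate_view_series(synth_config(p, n_days = 50, noise_sigma = 0.1))
#' head(sim$series)
#' @export
generate_view_series <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("'config' must come from synth_config()", call. = FALSE)
  }
  traj <- simulate_sir(config$true_params, config$S0, config$I0, R0 = 0,
                       t_end = config$n_days, dt = 1)
  G <- model_daily_views(traj)$G
  G <- pmax(G, 0)  # clip integrator-noise negatives at machine scale
  set.seed(config$seed)
  noisy <- if (config$noise_sigma == 0) {
    G
  } else if (config$noise == "lognormal") {
    eps <- stats::rnorm(length(G), mean = 0, sd = config$noise_sigma)
    G * exp(eps - config$noise_sigma^2 / 2)
  } else {
    stats::rpois(length(G), G)
  }
  list(series = view_series(c(0, noisy)),
       truth = view_series(c(0, G)),
       trajectory = traj,
       config = config)
}
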