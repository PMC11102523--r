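#' Configuration for the lineage-tracking agent-based model
#'
#' The stochastic counterpart of the mean-field model advances an agent
#' population in discrete steps of length `tau`. Each agent is
#' susceptible, infected (actively sharing) or recovered, and every
#' viewer carries a *lineage* label tracing the root of its infection
#' chain: lineage A for chains rooted in the initially infected agents
#' (Group A) and lineage B for chains rooted in an agent recruited by
#' advertising (Group B). The per-step transition probabilities `tau *
#' beta` and `tau * alpha` must not exceed 1.
#'
#' @param params a [model_params()] object.
#' @param O0,P0,Q0 initial susceptible / infected / recovered agent
#'   counts (nonnegative integers).
#' @param tau step length (days), `> 0`.
#' @param n_steps number of steps to simulate.
#' @param seed integer RNG seed.
#' @param realizations ensemble size for [abm_ensemble()].
#' @return An `abm_config` list.
#' @export
abm_config <- function(params, O0, P0, Q0 = 0, tau = 1, n_steps,
                       seed = 1L, realizations = 1L) {
  stopifnot_params(params)
  counts <- c(O0, P0, Q0)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("initial agent counts must be nonnegative integers", call. = FALSE)
  }
  if (tau <= 0) stop("'tau' must be positive", call. = FALSE)
  if (tau * params$beta > 1 || tau * params$alpha > 1) {
    stop(sprintf(
      "per-step probabilities exceed 1 (tau*beta = %g, tau*alpha = %g); use a smaller tau",
      tau * params$beta, tau * params$alpha), call. = FALSE)
  }
  if (n_steps < 1) stop("'n_steps' must be at least 1", call. = FALSE)
  if (realizations < 1) stop("'realizations' must be at least 1", call. = FALSE)
  structure(
    list(params = params, O0 = as.integer(O0), P0 = as.integer(P0),
         Q0 = as.integer(Q0), tau = tau, n_steps = as.integer(n_steps),
         seed = as.integer(seed), realizations = as.integer(realizations)),
    class = "abm_config"
  )
}

# Agent state codes
.SUS <- 1L
.INF <- 2L
.REC <- 3L
# Lineage codes: 0 none (susceptible), 1 = A (seeded sharers), 2 = B (advertising)
.LIN_NONE <- 0L
.LIN_A <- 1L
.LIN_B <- 2L

new_agent_population <- function(O0, P0, Q0) {
  state <- rep(c(.SUS, .INF, .REC), times = c(O0, P0, Q0))
  # Initially infected agents are the Group A roots, generation 1.
  # Any initially recovered agents are treated as exhausted Group A viewers.
  lineage <- rep(c(.LIN_NONE, .LIN_A, .LIN_A), times = c(O0, P0, Q0))
  generation <- rep(c(0L, 1L, 1L), times = c(O0, P0, Q0))
  list(state = state, lineage = lineage, generation = generation,
       arrival_carry = 0)
}

#' Advance the agent population by one step
#'
#' One update of length `tau`, in four phases whose intensities are all
#' frozen at the start-of-step counts `O(t)`, `P(t)` and the fixed
#' reference population `N`:
#' \enumerate{
#' \item \emph{Contact}: `P(t) * M/N` sharing attempts (stochastically
#'   rounded), where `M` is the current agent count; each draws a sharer
#'   uniformly with replacement and the targets are drawn uniformly from
#'   the whole current population, distinct within the step. A
#'   susceptible target converts with probability `tau * beta` - to
#'   infected with probability `beta1/beta`, otherwise straight to
#'   recovered - inheriting the sharer's lineage and `generation + 1`.
#'   The `M/N` attempt scaling keeps the expected conversion flux at the
#'   mean-field `tau * beta * P * O / N` with `N` the fixed reference
#'   population, even as arrivals grow `M` past `N`.
#' \item \emph{Advertising}: `K ~ Poisson(tau * gamma * N^2 / (N + P(t)))`
#'   susceptibles (capped at the number available) become infected with
#'   lineage B, generation 1.
#' \item \emph{Arrivals}: `floor(b*N*tau + carry)` new susceptible agents
#'   join; the fractional remainder carries to the next step so cumulative
#'   inflow matches `b*N*t` exactly.
#' \item \emph{Recovery}: each agent infected at the start of the step
#'   recovers independently with probability `tau * alpha`.
#' }
#' The expected one-step increment of (O, P, Q) matches `tau` times the
#' mean-field right-hand side to first order in `tau`.
#'
#' @param pop an agent population as built internally by [abm_run()].
#' @param params a [model_params()] object.
#' @param tau step length (days).
#' @param N reference population size used in all rates (held at the
#'   initial population size even as arrivals accumulate).
#' @return The updated population.
#' @keywords internal
abm_step <- function(pop, params, tau, N) {
  state0 <- pop$state
  inf_idx <- which(state0 == .INF)
  P0 <- length(inf_idx)
  M <- length(state0)

  state <- state0
  lineage <- pop$lineage
  generation <- pop$generation

  # Phase 1: contact. P(t) attempts; targets drawn from the whole current
  # population (size M), so a hit on a non-susceptible does nothing. The
  # conversion probability carries a factor M/N: the mean-field contact
  # flux is beta*P*O/N with N the *fixed* reference population, while a
  # uniform target is susceptible with probability O/M, and M outgrows N
  # as arrivals accumulate.
  if (P0 > 0L && params$beta > 0) {
    # Attempts are scaled by M/N (stochastically rounded): a uniform target
    # is susceptible with probability O/M, so P*M/N attempts give the
    # mean-field flux beta*P*O/N with N the fixed reference population.
    n_att_real <- P0 * M / N
    n_att <- floor(n_att_real) + (stats::runif(1L) < n_att_real %% 1)
    # Sharers are drawn with replacement (a busy sharer can convert several
    # targets in a step); targets are distinct within the step, since an
    # agent can watch the video at most once.
    sharer <- inf_idx[sample.int(P0, n_att, replace = TRUE)]
    target <- sample.int(M, min(n_att, M))
    hit <- which(stats::runif(length(target)) < tau * params$beta &
                   state0[target] == .SUS)
    if (length(hit) > 0L) {
      tgt <- target[hit]
      to_inf <- stats::runif(length(hit)) < params$beta1 / params$beta
      state[tgt] <- ifelse(to_inf, .INF, .REC)
      lineage[tgt] <- lineage[sharer[hit]]
      generation[tgt] <- generation[sharer[hit]] + 1L
    }
  }

  # Phase 2: advertising, mean frozen at the start-of-step sharer count.
  if (params$gamma > 0) {
    K <- stats::rpois(1L, tau * advertising_load(params$gamma, N, P0))
    sus_now <- which(state == .SUS)
    K <- min(K, length(sus_now))
    if (K > 0L) {
      picked <- sus_now[sample.int(length(sus_now), K)]
      state[picked] <- .INF
      lineage[picked] <- .LIN_B
      generation[picked] <- 1L
    }
  }

  # Phase 3: arrivals with fractional carry.
  inflow <- params$b * N * tau + pop$arrival_carry
  n_new <- floor(inflow)
  pop$arrival_carry <- inflow - n_new
  if (n_new > 0L) {
    state <- c(state, rep(.SUS, n_new))
    lineage <- c(lineage, rep(.LIN_NONE, n_new))
    generation <- c(generation, rep(0L, n_new))
  }

  # Phase 4: recovery of agents that were infected at the start of the step.
  if (P0 > 0L && params$alpha > 0) {
    rec <- inf_idx[stats::runif(P0) < tau * params$alpha]
    state[rec] <- .REC
  }

  pop$state <- state
  pop$lineage <- lineage
  pop$generation <- generation
  pop
}

count_population <- function(pop) {
  c(O = sum(pop$state == .SUS),
    P = sum(pop$state == .INF),
    Q = sum(pop$state == .REC),
    typeA = sum(pop$lineage == .LIN_A),
    typeB = sum(pop$lineage == .LIN_B))
}

#' Run a single realization of the agent-based model
#'
#' Simulates `n_steps` updates from the initial population (the `P0`
#' seeded sharers carry lineage A, generation 1) and records the
#' compartment counts and the lineage-attributed viewer counts (Type A:
#' chains rooted in the seeded sharers; Type B: chains rooted in an
#' advertising recruit) after every step. Deterministic given the seed.
#'
#' @param config an [abm_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return An `abm_result`: data frame with columns `t`, `O`, `P`, `Q`,
#'   `typeA`, `typeB` (one row per step, including the initial state) and
#'   attributes `seed` and `config`.
#' @export
abm_run <- function(config, seed = NULL) {
  if (!inherits(config, "abm_config")) {
    stop("'config' must come from abm_config()", call. = FALSE)
  }
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  N <- config$O0 + config$P0 + config$Q0
  pop <- new_agent_population(config$O0, config$P0, config$Q0)
  counts <- matrix(0L, nrow = config$n_steps + 1L, ncol = 5L)
  counts[1L, ] <- count_population(pop)
  for (k in seq_len(config$n_steps)) {
    pop <- abm_step(pop, config$params, config$tau, N)
    counts[k + 1L, ] <- count_population(pop)
  }
  out <- data.frame(t = (0:config$n_steps) * config$tau, counts)
  names(out) <- c("t", "O", "P", "Q", "typeA", "typeB")
  structure(out, seed = seed, config = config,
            class = c("abm_result", "data.frame"))
}

# Child seeds for ensemble members: drawn once from the master seed so the
# ensemble is reproducible and members are independent.
derive_child_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run an ensemble of agent-based realizations
#'
#' Repeats [abm_run()] with child seeds derived reproducibly from the
#' master seed and averages the count paths element-wise. The ensemble
#' mean approximates the mean-field trajectory increasingly well as the
#' ensemble grows.
#'
#' @param config an [abm_config()] with `realizations >= 1`.
#' @return List of class `abm_ensemble` with `mean` (data frame `t`, `O`,
#'   `P`, `Q`, `typeA`, `typeB` of ensemble means), `runs` (list of the
#'   per-realization `abm_result`s) and `seeds`.
#' @export
abm_ensemble <- function(config) {
  if (!inherits(config, "abm_config")) {
    stop("'config' must come from abm_config()", call. = FALSE)
  }
  seeds <- derive_child_seeds(config$seed, config$realizations)
  runs <- lapply(seeds, function(s) abm_run(config, seed = s))
  cols <- c("O", "P", "Q", "typeA", "typeB")
  acc <- Reduce(`+`, lapply(runs, function(r) as.matrix(r[cols])))
  rownames(acc) <- NULL
  mean_df <- data.frame(t = runs[[1L]]$t, acc / length(runs))
  names(mean_df) <- c("t", cols)
  structure(list(mean = mean_df, runs = runs, seeds = seeds),
            class = "abm_ensemble")
}

#' @export
print.abm_ensemble <- function(x, ...) {
  n <- length(x$runs)
  last <- x$mean[nrow(x$mean), ]
  cat(sprintf("ABM ensemble: %d realizations, %d steps\n", n, nrow(x$mean) - 1L))
  cat(sprintf("  final means: O = %.1f, P = %.1f, Q = %.1f, typeA = %.1f, typeB = %.1f\n",
              last$O, last$P, last$Q, last$typeA, last$typeB))
  invisible(x)
}
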