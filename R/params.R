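#' Model parameters for the sharing-plus-advertising SIR model
#'
#' Bundles the five rate constants of the model and validates the
#' orderings the theory relies on. `beta` is the total contact rate
#' between susceptibles and sharers; a contact converts the susceptible
#' into an active sharer at rate `beta1` and directly into a recovered
#' viewer at rate `beta - beta1` (hence `beta > beta1`). `alpha` is the
#' rate at which sharers stop sharing, `b` the inflow rate of new
#' susceptibles (per head of the reference population), and `gamma` the
#' advertising rate: advertising recruits susceptibles at the rate
#' `gamma * N^2 / (N + I)`, maximal (`gamma * N`) when nobody is sharing
#' and vanishing as sharers proliferate.
#'
#' The existence/uniqueness and global-stability results for the interior
#' equilibrium hold in the *theory regime* `alpha > b > gamma`; the
#' returned object carries a `theory_regime` flag, and the equilibrium
#' functions refuse to run outside it.
#'
#' @param beta contact rate (per day), `> 0`.
#' @param beta1 conversion-to-sharer rate (per day), `0 <= beta1 < beta`.
#' @param alpha recovery (stop-sharing) rate (per day), `>= 0`.
#' @param b new-user inflow rate (per day), `>= 0`.
#' @param gamma advertising rate (per day), `>= 0`.
#'
#' @return An object of class `model_params`: a list with the five rates
#'   and the logical `theory_regime`.
#' @examples
#' p <- model_params(beta = 0.4, beta1 = 0.1, alpha = 0.03, b = 0.02, gamma = 0.002)
#' p$theory_regime  # TRUE: alpha > b > gamma
#' @export
model_params <- function(beta, beta1, alpha, b, gamma) {
  rates <- c(beta = beta, beta1 = beta1, alpha = alpha, b = b, gamma = gamma)
  if (!all(is.finite(rates))) {
    stop("all rates must be finite numbers", call. = FALSE)
  }
  if (any(rates < 0)) {
    stop("all rates must be nonnegative", call. = FALSE)
  }
  if (beta <= beta1) {
    stop("'beta' must exceed 'beta1' (contacts cannot create sharers faster than viewers)",
         call. = FALSE)
  }
  structure(
    list(beta = beta, beta1 = beta1, alpha = alpha, b = b, gamma = gamma,
         theory_regime = (alpha > b) && (b > gamma)),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Sharing + advertising SIR parameters (per day)\n")
  cat(sprintf("  beta   = %g   (contact)\n", x$beta))
  cat(sprintf("  beta1  = %g   (conversion to sharer; beta1/beta = %.4f)\n",
              x$beta1, x$beta1 / x$beta))
  cat(sprintf("  alpha  = %g   (stop sharing)\n", x$alpha))
  cat(sprintf("  b      = %g   (new-user inflow)\n", x$b))
  cat(sprintf("  gamma  = %g   (advertising)\n", x$gamma))
  cat(sprintf("  theory regime (alpha > b > gamma): %s\n",
              if (x$theory_regime) "yes" else "no"))
  invisible(x)
}

is_model_params <- function(x) inherits(x, "model_params")

stopifnot_params <- function(params) {
  if (!is_model_params(params)) {
    stop("'params' must be created with model_params()", call. = FALSE)
  }
  invisible(params)
}

require_theory_regime <- function(params) {
  stopifnot_params(params)
  if (!params$theory_regime) {
    stop("the equilibrium theory requires alpha > b > gamma; ",
         sprintf("got alpha = %g, b = %g, gamma = %g. ",
                 params$alpha, params$b, params$gamma),
         "Existence/uniqueness and stability are unproven outside this regime, ",
         "so no equilibrium is returned.", call. = FALSE)
  }
  invisible(params)
}
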