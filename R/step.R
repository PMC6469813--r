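#' One synchronous update step (reference implementation)
#'
#' Advances an explicit neuron state by one time step using the same update
#' rules as [simulate_cros()], written in plain R. This is the readable
#' reference form of the dynamics: it exposes the state variables
#' (synaptic current `I`, spiking-rate variable `R_S`, binary spikes `S`)
#' and accepts the uniform draws explicitly, so fixed points, decay factors
#' and reset behaviour can be verified exactly. For production runs use
#' [simulate_cros()], whose compiled core applies the identical recurrences.
#'
#' Update order (all right-hand sides use the incoming state):
#' `R_S' = (R_S + I) * (1 - dt/tau_P) + P0 * dt/tau_P`,
#' `I' = (I + W^T S) * (1 - dt/tau_I)`, spikes drawn with probability
#' `clamp(R_S', 0, 1)` (probability 1 when `R_S' >= 1`, 0 at `R_S' <= 0`),
#' then `R_S'` of spiking neurons is reset to the type-specific value.
#'
#' @param state List with numeric `I`, `R_S` and binary `S`, each of length
#'   `L^2` (use [initial_state()] for the zeroed start).
#' @param topology A `cros_topology`.
#' @param params A [cros_params()] record.
#' @param draws Optional vector of uniforms in `[0, 1)`, one per neuron, to
#'   make the spike draw deterministic; defaults to `runif`.
#' @return The advanced state (same shape), with attribute `A` giving the
#'   step's spike count.
#' @examples
#' net <- build_network(L = 10, r_E = 0.2, r_I = 0.5, seed = 1)
#' st <- initial_state(net)
#' st <- cros_step(st, net)
#' attr(st, "A")
#' @export
cros_step <- function(state, topology, params = cros_params(),
                      draws = NULL) {
  stopifnot(inherits(topology, "cros_topology"))
  n <- topology$L^2
  stopifnot(length(state$I) == n, length(state$R_S) == n,
            length(state$S) == n)
  if (any(!is.finite(state$I)) || any(!is.finite(state$R_S)))
    stop("non-finite neuron state (parameter blow-up)")
  is_exc <- topology$is_excitatory
  decay_p <- ifelse(is_exc, 1 - params$dt / params$tau_P_exc,
                    1 - params$dt / params$tau_P_inh)
  p0_term <- ifelse(is_exc, params$P0_exc * params$dt / params$tau_P_exc,
                    params$P0_inh * params$dt / params$tau_P_inh)
  R_new <- (state$R_S + state$I) * decay_p + p0_term
  input <- as.numeric(Matrix::crossprod(topology$weights, state$S))
  I_new <- (state$I + input) * (1 - params$dt / params$tau_I)
  p <- pmin(pmax(R_new, 0), 1)
  if (is.null(draws)) draws <- stats::runif(n)
  S_new <- as.integer(R_new >= 1 | draws < p)
  R_new[S_new == 1L] <- ifelse(is_exc[S_new == 1L], params$reset_exc,
                               params$reset_inh)
  out <- list(I = I_new, R_S = R_new, S = S_new)
  attr(out, "A") <- sum(S_new)
  out
}

#' Zeroed initial state for the reference stepper
#'
#' @param topology A `cros_topology`.
#' @return State list with `I`, `R_S`, `S` all zero.
#' @export
initial_state <- function(topology) {
  n <- topology$L^2
  list(I = numeric(n), R_S = numeric(n), S = integer(n))
}
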