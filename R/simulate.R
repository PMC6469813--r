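#' Neuron dynamics parameters
#'
#' Default parameters of the stochastic neuron update: synaptic-current
#' decay time `tau_I` (ms), rate-variable decay times `tau_P` for
#' excitatory/inhibitory neurons (ms), background spiking probability `P0`
#' (per step; zero for inhibitory neurons), post-spike reset values of the
#' rate variable, and the time step `dt` (ms).
#'
#' @param tau_I Synaptic current decay constant, ms.
#' @param tau_P_exc,tau_P_inh Rate-variable decay constants, ms.
#' @param P0_exc,P0_inh Background spiking probabilities.
#' @param reset_exc,reset_inh Post-spike reset of the rate variable.
#' @param dt Time step, ms.
#' @param current_timing Which current enters the rate-variable update:
#'   `"previous"` (the previous step's published current; default) or
#'   `"updated"` (the current already updated with this step's synaptic
#'   input), a sensitivity switch for the simultaneous-update ambiguity.
#' @return A named list of class `cros_params`.
#' @export
cros_params <- function(tau_I = 9, tau_P_exc = 9, tau_P_inh = 12,
                        P0_exc = 1e-6, P0_inh = 0,
                        reset_exc = -2, reset_inh = -20, dt = 1,
                        current_timing = c("previous", "updated")) {
  current_timing <- match.arg(current_timing)
  structure(list(tau_I = tau_I, tau_P_exc = tau_P_exc, tau_P_inh = tau_P_inh,
                 P0_exc = P0_exc, P0_inh = P0_inh,
                 reset_exc = reset_exc, reset_inh = reset_inh, dt = dt,
                 current_timing = current_timing),
            class = "cros_params")
}

#' Simulate the CROS network
#'
#' Runs the synchronous stochastic update from a zeroed initial state
#' (currents, rate variables and spikes all zero) and records the population
#' activity `A(t)` = total number of spikes per step. Each step updates, in
#' this order and using only the previous step's published state on all
#' right-hand sides: the rate variable
#' `R_S <- (R_S + I) * (1 - dt/tau_P) + P0 * dt/tau_P` (with the previous
#' step's current `I`), the current
#' `I <- (I + W^T S) * (1 - dt/tau_I)`, the Bernoulli spike draw with
#' probability `clamp(R_S, 0, 1)` (one uniform per neuron, fixed order), and
#' the post-spike reset of `R_S`. Identical `(topology, n_steps, seed)`
#' yield bit-identical traces.
#'
#' @param topology A [build_network()] result.
#' @param n_steps Number of 1 ms steps (the reference run length is `2^20`).
#' @param seed Dynamics seed (independent of the disorder seed).
#' @param params A [cros_params()] record.
#' @param keep_raster If `TRUE`, also return per-spike `(t, neuron)` pairs.
#' @param init Optional initial state (list with `I`, `R_S`, `S` of length
#'   `L^2`, as in [initial_state()]); default is the zeroed state.
#' @return An object of class `cros_trace`: list with integer vector `A`,
#'   `dt`, `n_steps`, `L`, `params`, `seed` and optionally `raster`.
#' @examples
#' net <- build_network(L = 10, r_E = 0.2, r_I = 0.5, seed = 1)
#' tr <- simulate_cros(net, n_steps = 1000, seed = 2)
#' summary(tr$A)
#' @export
simulate_cros <- function(topology, n_steps, seed = 1L,
                          params = cros_params(), keep_raster = FALSE,
                          init = NULL) {
  stopifnot(inherits(topology, "cros_topology"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 0L) stop("'n_steps' must be >= 0")
  n <- topology$L^2
  if (n_steps == 0L) {
    return(structure(list(A = integer(0), dt = params$dt, n_steps = 0L,
                          L = topology$L, params = params,
                          seed = as.integer(seed)),
                     class = "cros_trace"))
  }
  is_exc <- topology$is_excitatory
  decay_p <- ifelse(is_exc, 1 - params$dt / params$tau_P_exc,
                    1 - params$dt / params$tau_P_inh)
  p0_term <- ifelse(is_exc, params$P0_exc * params$dt / params$tau_P_exc,
                    params$P0_inh * params$dt / params$tau_P_inh)
  reset_val <- ifelse(is_exc, params$reset_exc, params$reset_inh)
  decay_i <- 1 - params$dt / params$tau_I

  # t(W) in compressed-column form: column j = outgoing synapses of neuron j
  Wt <- methods::as(methods::as(Matrix::t(topology$weights),
                                "generalMatrix"), "CsparseMatrix")
  if (is.null(init)) {
    I0 <- numeric(0); R0 <- numeric(0); S0 <- integer(0)
  } else {
    stopifnot(length(init$I) == n, length(init$R_S) == n,
              length(init$S) == n)
    I0 <- as.numeric(init$I); R0 <- as.numeric(init$R_S)
    S0 <- as.integer(init$S)
  }
  # spike-draw stream keyed by dynamics seed and disorder seed jointly
  res <- .sim_core(n, n_steps, Wt@p, Wt@i, Wt@x,
                   decay_p, p0_term, reset_val, decay_i, keep_raster,
                   as.numeric(seed), as.numeric(topology$seed),
                   I0, R0, S0,
                   identical(params$current_timing, "updated"))
  out <- list(A = res$A, dt = params$dt, n_steps = n_steps, L = topology$L,
              params = params, seed = as.integer(seed))
  if (keep_raster) out$raster <- res$raster
  structure(out, class = "cros_trace")
}

#' @exportS3Method base::print
print.cros_trace <- function(x, ...) {
  cat(sprintf("CROS trace: %d steps of %g ms, L = %d, dynamics seed %d\n",
              x$n_steps, x$dt, x$L, x$seed))
  if (x$n_steps > 0)
    cat(sprintf("  mean A = %.3f, max A = %d\n", mean(x$A), max(x$A)))
  invisible(x)
}

#' Per-neuron mean firing rate of a trace
#'
#' Mean spikes per neuron per step, `mean(A) / L^2`; rises together with the
#' spectral order parameter across the oscillation transition and can serve
#' as an alternative order parameter.
#' @param trace A `cros_trace`.
#' @return Scalar firing rate (spikes / neuron / step).
#' @export
firing_rate <- function(trace) {
  stopifnot(inherits(trace, "cros_trace"))
  if (trace$n_steps == 0) return(NA_real_)
  mean(trace$A) / trace$L^2
}
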