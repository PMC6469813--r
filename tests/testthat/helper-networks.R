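# Shared fixtures built in code. Expensive full-protocol simulations are
# memoized per session so independent test blocks can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

# hand-built topology with arbitrary weights, for dynamics oracles
manual_topology <- function(L, weights, is_excitatory, seed = 1L) {
  structure(list(L = L, ell = 1L, r_E = 1, r_I = 1, exc_fraction = 0.75,
                 is_excitatory = is_excitatory,
                 weights = Matrix::Matrix(weights, sparse = TRUE),
                 seed = as.integer(seed), normalization = "neighborhood"),
            class = "cros_topology")
}

# isolated population: n neurons, no synapses
isolated_topology <- function(L, all_excitatory = TRUE) {
  n <- L^2
  manual_topology(L, matrix(0, n, n),
                  rep(all_excitatory, n))
}

# full L = 50 protocol run at one parameter point, cached
protocol_alpha_raw <- function(r_E, r_I = 0.6, n_real = 5, L = 50,
                               n_steps = 2^20) {
  key <- sprintf("alpha_%g_%g_%d_%d_%d", r_E, r_I, n_real, L, n_steps)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  alphas <- vapply(seq_len(n_real), function(k) {
    net <- build_network(L = L, ell = 7, r_E = r_E, r_I = r_I,
                         seed = 100 + k)
    tr <- simulate_cros(net, n_steps = n_steps, seed = 200 + k)
    dfa(tr$A)$alpha
  }, numeric(1))
  .fixture_cache[[key]] <- alphas
  alphas
}

# transition-point trace (L = 50, r_E = 0.14), cached
protocol_transition_trace <- function(seed_offset = 1) {
  key <- sprintf("trans_%d", seed_offset)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  net <- build_network(L = 50, ell = 7, r_E = 0.14, r_I = 0.60,
                       seed = 300 + seed_offset)
  tr <- simulate_cros(net, n_steps = 2^20, seed = 400 + seed_offset)
  .fixture_cache[[key]] <- tr
  tr
}
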