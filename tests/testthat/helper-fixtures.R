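# shared fixtures built in code

# linear death process on free sigma-V only: all other rates zero
pure_death_network <- function(k_deg = 0.01) {
  build_network(circuit_params(v0 = 0, v = 0, K = 60, n = 1,
                               k_deg = k_deg, k_B = 0, k_D = 0, k_C = 0))
}

# network in which nothing can ever fire
frozen_network <- function() {
  build_network(circuit_params(v0 = 0, v = 0, K = 1, n = 1,
                               k_deg = 0, k_B = 0, k_D = 0, k_C = 0))
}

# replay a recorded event sequence through the stoichiometry matrix,
# returning the running (sigv, rsiv, complex) path including the start state
replay_events <- function(network, init, channels) {
  st <- as.matrix(network$channels[, c("d_sigv", "d_rsiv", "d_complex")])
  path <- matrix(0, nrow = length(channels) + 1, ncol = 3)
  path[1, ] <- init
  if (length(channels) > 0)
    path[-1, ] <- matrix(init, length(channels), 3, byrow = TRUE) +
      apply(st[channels, , drop = FALSE], 2, cumsum)
  colnames(path) <- c("sigv", "rsiv", "complex")
  path
}

# simple step trace for activation-time checks
step_trace <- function(cell_id = 1, switch_at = 100, level = 100,
                       times = seq(0, 300, 10)) {
  tibble::tibble(cell_id = cell_id, time_min = times,
                 yfp = ifelse(times >= switch_at, level, 0))
}
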