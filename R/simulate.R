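#' Stochastic simulation of the circuit (Gillespie direct method)
#'
#' Simulates one exact sample path of the reaction network under a
#' piecewise-constant lysozyme protocol. Within each protocol segment the
#' standard direct-method step is used; at each segment boundary the
#' exponential clock is re-drawn with the updated propensities, which is
#' exact for piecewise-constant rates. States are recorded onto a uniform
#' grid by last-event-carried-forward. For a fixed
#' `(network, protocol, seed)` the trajectory is bit-identical across runs.
#'
#' @param network A [build_network()] object.
#' @param protocol A [step_protocol()] / [memory_protocol()] /
#'   [constant_protocol()] object; its duration sets the simulated horizon.
#' @param sample_interval Recording grid spacing (min, default 10, the
#'   imaging cadence of the experiments the model mirrors).
#' @param init Initial copy numbers `(sigv, rsiv, complex)`, default
#'   `(0, 0, 0)`.
#' @param seed Integer RNG seed.
#' @param record_events If `TRUE`, the fired reaction events (time, channel
#'   index) are attached as attribute `"events"`; intended for short runs and
#'   conservation-law checks.
#' @return A tibble with columns `time_min`, `sigv`, `rsiv`, `complex`, `L`
#'   and class `"sigv_trajectory"`; attributes `seed`, `variant`, `protocol`.
#' @examples
#' net <- build_network()
#' sim <- simulate_ssa(net, step_protocol(500, 1, 800), seed = 1)
#' @export
simulate_ssa <- function(network, protocol, sample_interval = 10,
                         init = c(0, 0, 0), seed = 1L,
                         record_events = FALSE) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(protocol, "sigv_protocol"))
  duration <- protocol_duration(protocol)
  if (duration <= 0) abort("protocol duration must be > 0")
  if (sample_interval <= 0) abort("sample_interval must be > 0")
  x0 <- check_state(init)
  res <- withr::with_seed(as.integer(seed),
    ssa_run_cpp(channel_matrix(network), protocol$start, protocol$L,
                duration, sample_interval, x0, record_events))
  out <- tibble(time_min = res$times,
                sigv = res$states[, 1],
                rsiv = res$states[, 2],
                complex = res$states[, 3],
                L = protocol_L_at(protocol, res$times))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "variant") <- network$variant
  attr(out, "protocol") <- protocol
  if (record_events)
    attr(out, "events") <- tibble(time = res$events$time,
                                  channel = res$events$channel)
  class(out) <- c("sigv_trajectory", class(out))
  out
}

#' Chemical Langevin simulation of the circuit
#'
#' Euler--Maruyama integration of the chemical Langevin equation: per step
#' each channel `j` contributes `nu_j * (a_j dt + sqrt(a_j dt) * xi_j)` with
#' independent standard normal `xi_j`. Negative excursions are handled by
#' full truncation: propensities are evaluated on the state clamped at zero,
#' so they stay non-negative. Deterministic for a fixed seed.
#'
#' @inheritParams simulate_ssa
#' @param dt Integration step (min). The default picks `dt` such that
#'   `max_j a_j * dt < 0.1` with the maximum taken over the channel
#'   propensities at the deterministic steady states of every protocol
#'   segment level (capped at `sample_interval`).
#' @return A `sigv_trajectory` tibble (continuous-valued states).
#' @export
simulate_cle <- function(network, protocol, dt = NULL, sample_interval = 10,
                         init = c(0, 0, 0), seed = 1L) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(protocol, "sigv_protocol"))
  duration <- protocol_duration(protocol)
  x0 <- check_state(init)
  if (is.null(dt)) dt <- cle_default_dt(network, protocol, x0)
  if (!is.numeric(dt) || dt <= 0) abort("dt must be > 0")
  dt <- min(dt, sample_interval)
  res <- withr::with_seed(as.integer(seed),
    cle_run_cpp(channel_matrix(network), protocol$start, protocol$L,
                duration, dt, sample_interval, x0))
  out <- tibble(time_min = res$times,
                sigv = res$states[, 1],
                rsiv = res$states[, 2],
                complex = res$states[, 3],
                L = protocol_L_at(protocol, res$times))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "variant") <- network$variant
  attr(out, "protocol") <- protocol
  attr(out, "dt") <- dt
  class(out) <- c("sigv_trajectory", class(out))
  out
}

# bound the fastest per-channel event rate over the protocol's stress levels
cle_default_dt <- function(network, protocol, init) {
  amax <- max(propensities(network, init,
                           max(protocol$L))$rate, na.rm = TRUE)
  for (L in unique(protocol$L)) {
    ss <- tryCatch(steady_state(network, L), error = function(e) NULL)
    if (!is.null(ss)) {
      a <- propensities(network, c(ss$sigv, ss$rsiv, ss$complex), L)$rate
      amax <- max(amax, a)
    }
  }
  if (!is.finite(amax) || amax <= 0) return(1)
  0.1 / amax
}

#' Simulate an ensemble of independent cells
#'
#' Runs `N` independent trajectories sharing one network and protocol.
#' Member seeds are drawn deterministically from `base_seed`, so the whole
#' ensemble is reproducible from a single integer.
#'
#' @inheritParams simulate_ssa
#' @param N Number of cells (>= 1).
#' @param base_seed Integer seed for the whole ensemble.
#' @param method `"ssa"` (exact) or `"cle"` (Langevin).
#' @param dt CLE step, passed through when `method = "cle"`.
#' @return A tibble with columns `cell_id`, `time_min`, `sigv`, `rsiv`,
#'   `complex`, `L`, class `"sigv_ensemble"`; attributes `seeds`, `variant`,
#'   `protocol`.
#' @examples
#' ens <- simulate_ensemble(build_network(), step_protocol(100, 1, 300),
#'                          N = 5, base_seed = 7)
#' @export
simulate_ensemble <- function(network, protocol, N, base_seed = 1L,
                              sample_interval = 10, init = c(0, 0, 0),
                              method = c("ssa", "cle"), dt = NULL) {
  method <- match.arg(method)
  if (N < 1) abort("N must be >= 1")
  seeds <- derive_seeds(base_seed, N)
  if (method == "cle" && is.null(dt))
    dt <- cle_default_dt(network, protocol, check_state(init))
  runs <- lapply(seq_len(N), function(i) {
    tr <- if (method == "ssa")
      simulate_ssa(network, protocol, sample_interval, init, seeds[i])
    else
      simulate_cle(network, protocol, dt, sample_interval, init, seeds[i])
    tr$cell_id <- i
    as_tibble(tr)[, c("cell_id", "time_min", "sigv", "rsiv", "complex", "L")]
  })
  out <- bind_rows(runs)
  attr(out, "seeds") <- seeds
  attr(out, "variant") <- network$variant
  attr(out, "protocol") <- protocol
  class(out) <- c("sigv_ensemble", class(out))
  out
}

# one base seed -> N distinct reproducible member seeds
derive_seeds <- function(base_seed, N) {
  withr::with_seed(as.integer(base_seed),
                   sample.int(.Machine$integer.max - 1L, N))
}

#' Samples from the stationary state of the circuit
#'
#' Draws `n` thinned samples of the free sigma-V count from a single long
#' simulation at constant lysozyme level, after a burn-in. Used to compare
#' the SSA and CLE stationary laws. Thinning does not fully decorrelate
#' consecutive samples (the slowest relaxation time is `1/k_deg`); the
#' samples estimate the stationary distribution, not an i.i.d. sample.
#'
#' @inheritParams simulate_ssa
#' @param L Constant lysozyme level.
#' @param n Number of samples.
#' @param burn_in Discarded initial time (min).
#' @param thin Time between retained samples (min).
#' @param method `"ssa"` or `"cle"`.
#' @param dt CLE step (`NULL` = default rule).
#' @return Numeric vector of `n` free sigma-V values.
#' @export
stationary_samples <- function(network, L = 1, n = 500, burn_in = 500,
                               thin = 50, method = c("ssa", "cle"),
                               seed = 1L, dt = NULL) {
  method <- match.arg(method)
  ss <- steady_state(network, L)
  init <- round(c(ss$sigv, ss$rsiv, ss$complex))
  duration <- burn_in + n * thin
  prot <- constant_protocol(L, duration)
  tr <- if (method == "ssa")
    simulate_ssa(network, prot, sample_interval = thin, init = init,
                 seed = seed)
  else
    simulate_cle(network, prot, dt = dt, sample_interval = thin,
                 init = init, seed = seed)
  vals <- tr$sigv[tr$time_min > burn_in - 1e-9]
  utils::tail(vals, n)
}
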