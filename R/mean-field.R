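#' Mean-field time derivatives
#'
#' Deterministic (mean-field) right-hand side of the circuit: the sum of
#' `propensity * stoichiometry` over all reaction channels, evaluated at a
#' continuous state. Each term corresponds one-to-one to a reaction channel of
#' the network, so the ODE is the exact macroscopic companion of the
#' stochastic model and serves as a verification oracle for the simulators.
#'
#' @inheritParams propensities
#' @return Named numeric vector `(sigv, rsiv, complex)` of time derivatives
#'   (molecules/min).
#' @examples
#' mean_field_rhs(build_network(), c(0, 0, 0), L = 0) # leak only: (0.1, 0.1, 0)
#' @export
mean_field_rhs <- function(network, state, L = 0) {
  pr <- propensities(network, state, L)$rate
  ch <- network$channels
  d <- c(sum(pr * ch$d_sigv), sum(pr * ch$d_rsiv), sum(pr * ch$d_complex))
  setNames(d, c("sigv", "rsiv", "complex"))
}

# deSolve-compatible derivative function for a fixed L
desolve_func <- function(network, L) {
  function(t, y, parms) {
    list(mean_field_rhs(network, pmax(y, 0), L))
  }
}

#' Deterministic solution of the mean-field ODE under a stress protocol
#'
#' Integrates the mean-field equations segment by segment over a
#' piecewise-constant lysozyme protocol using `deSolve::lsoda`.
#'
#' @inheritParams propensities
#' @param protocol A [step_protocol()] / [memory_protocol()] object.
#' @param times Output time grid (min), covering `[0, duration]`.
#' @param init Initial continuous state, default `(0, 0, 0)`.
#' @return A tibble with columns `time_min`, `sigv`, `rsiv`, `complex`, `L`.
#' @export
mean_field_path <- function(network, protocol, times, init = c(0, 0, 0)) {
  stopifnot(inherits(network, "reaction_network"))
  segs <- protocol_segments(protocol)
  y <- as.numeric(init)
  out <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    t0 <- segs$start[k]
    t1 <- segs$end[k]
    tt <- times[times >= t0 - 1e-9 & times <= t1 + 1e-9]
    # always integrate across the full segment so the end state is carried over
    grid <- sort(unique(c(t0, tt, t1)))
    sol <- deSolve::lsoda(y, grid, desolve_func(network, segs$L[k]),
                          rtol = 1e-9, atol = 1e-9)
    keep <- sol[sol[, 1] %in% tt, , drop = FALSE]
    out[[k]] <- tibble(time_min = keep[, 1], sigv = keep[, 2],
                       rsiv = keep[, 3], complex = keep[, 4], L = segs$L[k])
    y <- as.numeric(sol[nrow(sol), 2:4])
  }
  res <- bind_rows(out)
  res[!duplicated(res$time_min), ]
}

#' Deterministic steady state of the circuit
#'
#' Finds a non-negative fixed point of the mean-field equations at constant
#' lysozyme level `L`. The system is integrated from the zero state for a
#' long horizon and the end point is polished by damped Newton iteration on
#' the right-hand side. When a distinct stable fixed point is reachable from
#' a high-sigma-V initial condition, the returned state is still the one
#' reached from the zero state and the result is flagged multistable.
#'
#' @inheritParams propensities
#' @param t_max Integration horizon used to approach the fixed point (min).
#' @param tol Convergence tolerance on the max absolute derivative.
#' @return A one-row tibble `sigv`, `rsiv`, `complex`, `L`, `multistable`.
#' @examples
#' steady_state(build_network(), L = 0)
#' @export
steady_state <- function(network, L = 0, t_max = 1e5, tol = 1e-9) {
  stopifnot(inherits(network, "reaction_network"))
  low <- settle(network, L, c(0, 0, 0), t_max, tol)
  p <- network$params
  high0 <- c((p$v0 + p$v) / max(p$k_deg, 1e-6), 0, 0)
  high <- settle(network, L, high0, t_max, tol)
  rel <- max(abs(high - low)) / max(1, max(abs(low)))
  tibble(sigv = low[1], rsiv = low[2], complex = low[3], L = L,
         multistable = rel > 1e-3)
}

settle <- function(network, L, init, t_max, tol) {
  f <- function(y) mean_field_rhs(network, y, L)
  tt <- unique(c(0, 10^(seq(0, log10(t_max), length.out = 12))))
  sol <- deSolve::lsoda(as.numeric(init), tt, desolve_func(network, L),
                        rtol = 1e-10, atol = 1e-10, maxsteps = 50000)
  y <- pmax(as.numeric(sol[nrow(sol), 2:4]), 0)
  # damped Newton polish with finite-difference Jacobian
  for (iter in 1:50) {
    r <- f(y)
    if (max(abs(r)) < tol) break
    J <- matrix(0, 3, 3)
    h <- pmax(abs(y), 1) * 1e-7
    for (j in 1:3) {
      yp <- y; yp[j] <- yp[j] + h[j]
      ym <- y; ym[j] <- max(ym[j] - h[j], 0)
      J[, j] <- (f(yp) - f(ym)) / (yp[j] - ym[j])
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      y_new <- pmax(y + lam * step, 0)
      if (max(abs(f(y_new))) < max(abs(r)) || lam < 1e-4) break
      lam <- lam / 2
    }
    y <- y_new
  }
  if (max(abs(f(y))) > sqrt(tol))
    abort(paste0("steady_state did not converge: max |d/dt| = ",
                 format(max(abs(f(y))))))
  y
}
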