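#' Hill production rate of the operon
#'
#' Production propensity of the sigma-V operon as a function of the free
#' sigma-V copy number: `v0 + v * s^n / (s^n + K^n)`. The rate is bounded in
#' `[v0, v0 + v)`, equals `v0 + v/2` exactly at `s = K`, and is strictly
#' increasing in `s` when `v > 0`.
#'
#' @param sigv_free Free sigma-V copy number(s), >= 0. Vectorised.
#' @param params A [circuit_params()] object.
#' @return Production rate(s) in molecules/min.
#' @examples
#' hill_production_rate(0, circuit_params())   # leak only: 0.1
#' hill_production_rate(60, circuit_params())  # half-saturation: 1.35
#' @export
hill_production_rate <- function(sigv_free, params = circuit_params()) {
  validate_circuit_params(params)
  if (any(!is.finite(sigv_free)) || any(sigv_free < 0))
    abort("sigv_free must be non-negative and finite")
  sn <- sigv_free^params$n
  params$v0 + params$v * sn / (sn + params$K^params$n)
}

# channel kinds understood by the simulation engine
.KIND_CONST <- 0
.KIND_LINEAR <- 1
.KIND_BIMOLECULAR <- 2
.KIND_HILL <- 3
.KIND_CLEAVAGE <- 4

new_channel <- function(name, kind, c1 = 0, c2 = 0, c3 = 0, c4 = 0,
                        d_sigv = 0, d_rsiv = 0, d_complex = 0) {
  tibble(name = name, kind = kind, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
         d_sigv = d_sigv, d_rsiv = d_rsiv, d_complex = d_complex)
}

#' Build the reaction network of a circuit variant
#'
#' Assembles the reaction channels of the sigma-V circuit. The wild type has
#' seven channels: joint Hill-regulated production of sigma-V and RsiV,
#' first-order dilution of each of the three species, binding of free sigma-V
#' and RsiV into the complex, dissociation of the complex, and
#' lysozyme-dependent cleavage of the complex (releasing sigma-V, degrading
#' RsiV). Variants add or replace channels:
#'
#' * `second_copy_sigv` / `second_copy_rsiv`: one extra production channel of
#'   the single gene at the same Hill rate (a second promoter copy).
#' * `second_copy_operon`: a duplicate of the full joint production channel
#'   (equivalent to doubling `v0` and `v`).
#' * `feedback_broken`: the Hill production channel is replaced by a constant
#'   (constitutive) joint production at rate `magnitude`.
#' * `leak_sigv` / `leak_rsiv`: an added independent constant-rate channel
#'   producing only the named species at rate `magnitude`.
#' * `hill_override`: the wild-type network with the Hill coefficient replaced
#'   by `magnitude`.
#'
#' @param params A [circuit_params()] object.
#' @param variant A [circuit_variant()] object (default wild type).
#' @return A `reaction_network` object: a channel table plus the parameters
#'   and variant it was built from.
#' @examples
#' build_network(circuit_params())
#' build_network(variant = circuit_variant("feedback_broken", 1))
#' @export
build_network <- function(params = circuit_params(),
                          variant = circuit_variant("wild_type")) {
  validate_circuit_params(params)
  if (!inherits(variant, "circuit_variant"))
    abort("'variant' must be a circuit_variant object")

  p <- params
  if (variant$kind == "hill_override")
    p$n <- variant$magnitude

  hill <- function(name, d_sigv, d_rsiv) {
    new_channel(name, .KIND_HILL, c1 = p$v0, c2 = p$v, c3 = p$n, c4 = p$K,
                d_sigv = d_sigv, d_rsiv = d_rsiv)
  }

  production <- hill("production", 1, 1)
  if (variant$kind == "feedback_broken")
    production <- new_channel("production_constitutive", .KIND_CONST,
                              c1 = variant$magnitude, d_sigv = 1, d_rsiv = 1)

  channels <- bind_rows(
    production,
    new_channel("dilution_sigv", .KIND_LINEAR, c1 = p$k_deg, c2 = 0,
                d_sigv = -1),
    new_channel("dilution_rsiv", .KIND_LINEAR, c1 = p$k_deg, c2 = 1,
                d_rsiv = -1),
    new_channel("dilution_complex", .KIND_LINEAR, c1 = p$k_deg, c2 = 2,
                d_complex = -1),
    new_channel("binding", .KIND_BIMOLECULAR, c1 = p$k_B,
                d_sigv = -1, d_rsiv = -1, d_complex = 1),
    new_channel("dissociation", .KIND_LINEAR, c1 = p$k_D, c2 = 2,
                d_sigv = 1, d_rsiv = 1, d_complex = -1),
    new_channel("cleavage", .KIND_CLEAVAGE, c1 = p$k_C,
                d_sigv = 1, d_complex = -1)
  )

  extra <- switch(variant$kind,
    second_copy_sigv = hill("production_2x_sigv", 1, 0),
    second_copy_rsiv = hill("production_2x_rsiv", 0, 1),
    second_copy_operon = hill("production_2x_operon", 1, 1),
    leak_sigv = new_channel("leak_sigv", .KIND_CONST,
                            c1 = variant$magnitude, d_sigv = 1),
    leak_rsiv = new_channel("leak_rsiv", .KIND_CONST,
                            c1 = variant$magnitude, d_rsiv = 1),
    NULL
  )
  if (!is.null(extra)) channels <- bind_rows(channels, extra)

  structure(list(channels = channels, params = params, variant = variant),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> variant:", x$variant$kind, "-",
      nrow(x$channels), "channels\n")
  print(x$channels)
  invisible(x)
}

# numeric matrix consumed by the C++ engine
channel_matrix <- function(network) {
  ch <- network$channels
  as.matrix(ch[, c("kind", "c1", "c2", "c3", "c4",
                   "d_sigv", "d_rsiv", "d_complex")])
}

check_state <- function(state) {
  if (length(state) != 3 || any(!is.finite(state)) || any(state < 0))
    abort("state must be three non-negative finite counts (sigv, rsiv, complex)")
  as.numeric(state)
}

#' Per-channel reaction propensities
#'
#' Evaluates the propensity (firing rate, 1/min) of every channel of a
#' network at a given state and lysozyme level. Channels whose reactant count
#' is zero have propensity zero.
#'
#' @param network A [build_network()] object.
#' @param state Numeric length-3 state `(sigv, rsiv, complex)`, >= 0.
#' @param L Lysozyme level (>= 0); scales only the cleavage channel.
#' @return A tibble with one row per channel: `name`, `rate`.
#' @examples
#' propensities(build_network(), state = c(2, 3, 5), L = 1)
#' @export
propensities <- function(network, state, L = 0) {
  stopifnot(inherits(network, "reaction_network"))
  x <- check_state(state)
  if (!is.numeric(L) || length(L) != 1 || !is.finite(L) || L < 0)
    abort("L must be a single non-negative number")
  ch <- network$channels
  rate <- numeric(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    rate[i] <- switch(as.character(ch$kind[i]),
      "0" = ch$c1[i],
      "1" = ch$c1[i] * x[ch$c2[i] + 1],
      "2" = ch$c1[i] * x[1] * x[2],
      "3" = {
        if (x[1] <= 0) ch$c1[i]
        else {
          sn <- x[1]^ch$c3[i]
          ch$c1[i] + ch$c2[i] * sn / (sn + ch$c4[i]^ch$c3[i])
        }
      },
      "4" = ch$c1[i] * L * x[3]
    )
  }
  tibble(name = ch$name, rate = rate)
}

#' Apply one reaction event to a state
#'
#' Shifts the state by the stoichiometry vector of the indexed channel.
#'
#' @inheritParams propensities
#' @param channel Channel index (row of `network$channels`) or channel name.
#' @return The updated length-3 state.
#' @examples
#' apply_reaction(build_network(), c(2, 3, 5), "binding") # (1, 2, 6)
#' @export
apply_reaction <- function(network, state, channel) {
  stopifnot(inherits(network, "reaction_network"))
  x <- check_state(state)
  ch <- network$channels
  if (is.character(channel)) channel <- match(channel, ch$name)
  if (is.na(channel) || channel < 1 || channel > nrow(ch))
    abort("unknown reaction channel")
  out <- x + c(ch$d_sigv[channel], ch$d_rsiv[channel], ch$d_complex[channel])
  if (any(out < 0))
    abort("internal consistency error: reaction would drive a count negative")
  setNames(out, c("sigv", "rsiv", "complex"))
}
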