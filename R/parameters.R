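#' Rate constants of the sigma-V / RsiV circuit
#'
#' Bundles the eight rate constants of the simplified sigma-V operon model:
#' production of sigma-V and RsiV as one Hill-regulated operon, first-order
#' dilution of all species, reversible sigma-V:RsiV complex formation, and
#' lysozyme-dependent cleavage of the complex. The defaults are the published
#' wild-type parameter set for this circuit.
#'
#' @param v0 Operon leak production rate (molecules/min).
#' @param v Maximal operon production rate above leak (molecules/min).
#' @param K Apparent dissociation constant of the Hill activation (molecules).
#' @param n Hill coefficient (dimensionless, >= 1).
#' @param k_deg Dilution rate of all three species (1/min); stands in for
#'   growth dilution, matching the experimental division rate.
#' @param k_B Binding rate of free sigma-V and free RsiV (1/(molecule*min)).
#' @param k_D Dissociation rate of the complex (1/min).
#' @param k_C Base cleavage rate of the complex; the realised cleavage
#'   propensity is `L * k_C * complex` for lysozyme level `L` (1/min).
#'
#' @return A named list of class `"circuit_params"`.
#' @examples
#' circuit_params()
#' circuit_params(n = 1) # remove ultrasensitivity
#' @export
circuit_params <- function(v0 = 0.1, v = 2.5, K = 60, n = 2,
                           k_deg = 0.01, k_B = 10, k_D = 5, k_C = 0.05) {
  p <- list(v0 = v0, v = v, K = K, n = n,
            k_deg = k_deg, k_B = k_B, k_D = k_D, k_C = k_C)
  validate_circuit_params(p)
  structure(p, class = "circuit_params")
}

validate_circuit_params <- function(p) {
  needed <- c("v0", "v", "K", "n", "k_deg", "k_B", "k_D", "k_C")
  missing <- setdiff(needed, names(p))
  if (length(missing) > 0)
    abort(paste0("missing circuit parameter(s): ",
                 paste(missing, collapse = ", ")))
  for (nm in needed) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val < 0)
      abort(paste0("circuit parameter '", nm,
                   "' must be a single non-negative finite number"))
  }
  if (p$n < 1) abort("Hill coefficient 'n' must be >= 1")
  invisible(p)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>\n")
  cat(sprintf("  production: v0 = %g, v = %g molecules/min; K = %g molecules, n = %g\n",
              x$v0, x$v, x$K, x$n))
  cat(sprintf("  dilution:   k_deg = %g /min\n", x$k_deg))
  cat(sprintf("  complex:    k_B = %g /(molecule min), k_D = %g /min, k_C = %g /min\n",
              x$k_B, x$k_D, x$k_C))
  invisible(x)
}

#' Genetic variant of the circuit
#'
#' Describes a perturbation to the wild-type reaction network. Variants mirror
#' the strain constructions studied with this circuit: second chromosomal
#' copies of operon genes driven by the native promoter, a feedback-broken
#' operon under constitutive expression, gene-specific leaky baseline
#' production, and an override of the Hill coefficient.
#'
#' @param kind One of `"wild_type"`, `"second_copy_sigv"`,
#'   `"second_copy_rsiv"`, `"second_copy_operon"`, `"feedback_broken"`,
#'   `"leak_sigv"`, `"leak_rsiv"`, `"hill_override"`.
#' @param magnitude For `"feedback_broken"` the constitutive production rate
#'   (molecules/min, > 0); for the leak variants the added baseline rate
#'   (molecules/min, > 0); for `"hill_override"` the replacement Hill
#'   coefficient (>= 1). Ignored otherwise.
#' @return A list of class `"circuit_variant"`.
#' @examples
#' circuit_variant("second_copy_rsiv")
#' circuit_variant("feedback_broken", magnitude = 1)
#' @export
circuit_variant <- function(kind = c("wild_type", "second_copy_sigv",
                                     "second_copy_rsiv", "second_copy_operon",
                                     "feedback_broken", "leak_sigv",
                                     "leak_rsiv", "hill_override"),
                            magnitude = NULL) {
  kind <- match.arg(kind)
  needs_mag <- kind %in% c("feedback_broken", "leak_sigv", "leak_rsiv",
                           "hill_override")
  if (needs_mag) {
    if (is.null(magnitude) || !is.numeric(magnitude) || length(magnitude) != 1 ||
        !is.finite(magnitude))
      abort(paste0("variant '", kind, "' requires a numeric 'magnitude'"))
    if (kind == "hill_override" && magnitude < 1)
      abort("hill_override magnitude (the replacement Hill coefficient) must be >= 1")
    if (kind != "hill_override" && magnitude <= 0)
      abort(paste0("variant '", kind, "' requires magnitude > 0"))
  } else {
    magnitude <- NULL
  }
  structure(list(kind = kind, magnitude = magnitude),
            class = "circuit_variant")
}

#' @export
print.circuit_variant <- function(x, ...) {
  cat("<circuit_variant> ", x$kind,
      if (!is.null(x$magnitude)) sprintf(" (magnitude = %g)", x$magnitude),
      "\n", sep = "")
  invisible(x)
}

#' System-size scaling of the circuit parameters
#'
#' Scales the parameter set so that intensive (per-volume) mean-field dynamics
#' are unchanged while copy numbers grow by a factor `omega`: `v0`, `v` and
#' `K` are multiplied by `omega` and the bimolecular rate `k_B` is divided by
#' `omega`. As `omega` grows, stochastic trajectories per `omega` converge to
#' the deterministic mean-field solution, which is used as a verification
#' oracle for the simulators.
#'
#' @param params A [circuit_params()] object.
#' @param omega System-size factor (> 0).
#' @return A rescaled `circuit_params` object.
#' @export
scale_system_size <- function(params, omega) {
  stopifnot(inherits(params, "circuit_params"), omega > 0)
  circuit_params(v0 = params$v0 * omega, v = params$v * omega,
                 K = params$K * omega, n = params$n,
                 k_deg = params$k_deg, k_B = params$k_B / omega,
                 k_D = params$k_D, k_C = params$k_C)
}
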