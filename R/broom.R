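# broom-style tidiers: tidy() returns the per-arm summary table,
# glance() a one-row overview

tidy_summary <- function(x) as_tibble(x$summary)

#' @export
tidy.sigv_dose_response <- function(x, ...) tidy_summary(x)
#' @export
tidy.sigv_copy_number <- function(x, ...) tidy_summary(x)
#' @export
tidy.sigv_memory <- function(x, ...) tidy_summary(x)
#' @export
tidy.sigv_feedback <- function(x, ...) tidy_summary(x)
#' @export
tidy.sigv_leak_scan <- function(x, ...) tidy_summary(x)
#' @export
tidy.sigv_hill_check <- function(x, ...) tidy_summary(x)
#' @export
tidy.sigv_robustness <- function(x, ...) tidy_summary(x)

#' @export
glance.sigv_dose_response <- function(x, ...) {
  tibble(n_levels = nrow(x$summary), N_per_level = x$summary$N[1],
         seed = x$seed,
         activation_decreasing = !is.unsorted(-x$summary$mean_activation),
         steady_state_increasing = !is.unsorted(x$summary$mean_ss))
}

#' @export
glance.sigv_copy_number <- function(x, ...) {
  s <- x$summary
  tibble(n_variants = nrow(s), N = s$N[1], threshold = x$threshold,
         seed = x$seed,
         wt_fraction = s$fraction[s$variant == "wild_type"])
}

#' @export
glance.sigv_memory <- function(x, ...) {
  s <- x$summary[!is.na(x$summary$gap), ]
  tibble(n_gaps = nrow(s), N = x$summary$N[1], seed = x$seed,
         heterogeneity_nondecreasing = !is.unsorted(s$sd_activation),
         longest_gap_ks_p = s$ks_p[which.max(s$gap)])
}

#' @export
glance.sigv_feedback <- function(x, ...) {
  s <- x$summary
  wt <- s$mean_fold[s$arm == "wild_type"]
  tibble(wt_fold = wt, seed = x$seed,
         n_rates = sum(s$arm == "feedback_broken"),
         wt_exceeds_all = all(wt > s$mean_fold[s$arm == "feedback_broken"]))
}

#' @export
glance.sigv_leak_scan <- function(x, ...) {
  tibble(species = x$species, n_deltas = nrow(x$summary), seed = x$seed,
         fraction_monotone = if (x$species == "sigv")
           !is.unsorted(x$summary$fraction)
         else !is.unsorted(-x$summary$fraction))
}

#' @export
glance.sigv_hill_check <- function(x, ...) {
  tibble(n_values = nrow(x$summary), seed = x$seed,
         heterogeneity_increases_with_n = x$heterogeneity_increases_with_n)
}

#' @export
glance.sigv_robustness <- function(x, ...) {
  s <- x$summary[x$summary$param != "none", ]
  tibble(n_perturbations = nrow(s), sd_floor = x$sd_floor, seed = x$seed,
         fraction_dispersed = mean(s$dispersed))
}
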