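# ggplot2 autoplot methods for the package's result objects

#' @export
autoplot.sigv_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("sigv", "rsiv", "complex"),
                            names_to = "species", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$count,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "copy number", colour = NULL)
}

#' @export
autoplot.sigv_ensemble <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time_min, .data$sigv,
                               group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "time (min)", y = "free sigma-V (molecules)")
}

#' @export
autoplot.sigv_dose_response <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(factor(.data$L), .data$mean_activation)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_activation - .data$sd_activation,
      ymax = .data$mean_activation + .data$sd_activation), width = 0.2) +
    ggplot2::labs(x = "lysozyme level L", y = "activation time (min)")
}

#' @export
autoplot.sigv_copy_number <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$variant, .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fraction - .data$boot_sd,
                                        ymax = .data$fraction + .data$boot_sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL,
                  y = sprintf("fraction activated %g min after stress",
                              object$assay_delay)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.sigv_memory <- function(object, ...) {
  cv <- object$curves
  cv$arm <- ifelse(is.na(cv$gap), "control (naive)",
                   paste0("gap ", cv$gap, " min"))
  ggplot2::ggplot(cv, ggplot2::aes(.data$time, .data$fraction,
                                   colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time after (re)stress (min)",
                  y = "cumulative fraction activated", colour = NULL)
}

#' @export
autoplot.sigv_feedback <- function(object, ...) {
  s <- object$summary
  wt <- s$mean_fold[s$arm == "wild_type"]
  fb <- s[s$arm == "feedback_broken", ]
  ggplot2::ggplot(fb, ggplot2::aes(.data$rate, .data$mean_fold)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_fold - .data$sd_fold,
                                      ymax = .data$mean_fold + .data$sd_fold),
                         fill = "red", alpha = 0.2) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::geom_hline(yintercept = wt, colour = "blue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "constitutive production rate (molecules/min)",
                  y = "fold change (post / pre stress)")
}

#' @export
autoplot.sigv_leak_scan <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(.data$delta, .data$fraction)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$fraction - .data$boot_sd,
      ymax = .data$fraction + .data$boot_sd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("added %s leak rate (molecules/min)",
                              object$species),
                  y = "fraction activated")
}
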