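#' Per-cell activation times (half-maximum rule)
#'
#' Computes, for every cell in a long-format trace table, the time from
#' stress addition until the readout first crosses half of the cell's own
#' final (plateau) level. The final level is the mean of the readout over the
#' trailing `final_window` minutes of the trace; a cell is censored when the
#' readout never crosses half of that level within the observation window, or
#' when the final level does not exceed the cell's pre-stress mean
#' (a non-responder; see `require_rise`).
#'
#' @param data A data frame with one row per cell and frame; must contain
#'   `cell_id`, a time column `time_min` (min, uniform spacing per cell) and
#'   the readout column named by `value`.
#' @param value Readout column (tidy-select), e.g. `sigv` for model
#'   trajectories or `yfp` for reporter traces.
#' @param stress_time Time of stress addition (min).
#' @param final_window Length of the trailing window whose mean defines the
#'   final level (min, default 100).
#' @param prestress_window If not `NULL`, only the last `prestress_window`
#'   minutes before `stress_time` define the pre-stress mean (used e.g. when
#'   an earlier stress episode precedes the one being scored).
#' @param require_rise When `TRUE` (default) a cell whose final level does not
#'   exceed its pre-stress mean is censored as a non-responder; this guards
#'   against the degenerate case where a flat, never-responding trace trivially
#'   sits above half of its own flat level. Set to `FALSE` when the scored
#'   episode restresses cells that are known to have activated before, so that
#'   a cell still above its half-maximum at `stress_time` counts as activated
#'   immediately rather than as a non-responder.
#' @return A tibble with one row per cell: `cell_id`, `prestress_mean`,
#'   `final_level`, `half_max`, `activation_time` (min from stress, `NA` when
#'   censored) and `censored`.
#' @examples
#' tr <- tibble::tibble(cell_id = 1, time_min = seq(0, 200, 10),
#'                      yfp = c(rep(0, 10), rep(100, 11)))
#' activation_times(tr, yfp, stress_time = 60)
#' @export
activation_times <- function(data, value, stress_time, final_window = 100,
                             prestress_window = NULL, require_rise = TRUE) {
  stopifnot(is.data.frame(data), all(c("cell_id", "time_min") %in% names(data)))
  val <- enquo(value)
  df <- data %>%
    mutate(.value = eval_tidy(val, data)) %>%
    select("cell_id", "time_min", ".value") %>%
    arrange(.data$cell_id, .data$time_min)
  if (max(df$time_min) <= stress_time)
    abort("traces end before stress_time")
  pre_lo <- if (is.null(prestress_window)) -Inf else stress_time - prestress_window
  df %>%
    group_by(.data$cell_id) %>%
    summarise(
      prestress_mean = mean(.data$.value[.data$time_min < stress_time &
                                           .data$time_min >= pre_lo]),
      final_level = mean(.data$.value[.data$time_min >
                                        max(.data$time_min) - final_window]),
      half_max = .data$final_level / 2,
      activation_time = {
        post_t <- .data$time_min[.data$time_min >= stress_time]
        post_v <- .data$.value[.data$time_min >= stress_time]
        hit <- which(post_v >= .data$final_level / 2)
        if (length(hit) == 0) NA_real_ else post_t[hit[1]] - stress_time
      },
      .groups = "drop"
    ) %>%
    mutate(
      censored = is.na(.data$activation_time) |
        (require_rise & (!(.data$final_level > .data$prestress_mean) |
                           is.na(.data$prestress_mean))),
      activation_time = ifelse(.data$censored, NA_real_,
                               .data$activation_time)
    )
}

#' Cumulative activation curve
#'
#' Fraction of cells that have activated by each grid time. Censored cells
#' stay in the denominator, so the curve is monotone non-decreasing, bounded
#' by 1, and reaches 1 only if no cell is censored.
#'
#' @param summaries Output of [activation_times()].
#' @param grid Times (min, measured from stress addition) at which to
#'   evaluate the curve.
#' @return A tibble `time` (min from stress), `fraction`.
#' @export
cumulative_activation_curve <- function(summaries, grid) {
  stopifnot(is.data.frame(summaries),
            all(c("activation_time", "censored") %in% names(summaries)))
  if (nrow(summaries) == 0) abort("no cells in input")
  at <- summaries$activation_time[!summaries$censored]
  tibble(time = grid,
         fraction = vapply(grid, function(g) sum(at <= g) / nrow(summaries),
                           numeric(1)))
}

#' Fraction of activated cells from snapshots
#'
#' Snapshot statistic: the threshold is the mean of the pre-stress values
#' plus `k_sd` sample standard deviations, and a post-stress cell counts as
#' activated when its value exceeds the threshold strictly.
#'
#' @param pre_values Per-cell readout before stress (length >= 2).
#' @param post_values Per-cell readout at the assay time.
#' @param k_sd Threshold stringency in standard deviations (default 6).
#' @return Fraction of `post_values` above the threshold, with the threshold
#'   attached as attribute `"threshold"`.
#' @examples
#' fraction_activated_snapshot(c(9, 10, 11), c(10, 17, 10, 17)) # 0.5
#' @export
fraction_activated_snapshot <- function(pre_values, post_values, k_sd = 6) {
  if (length(pre_values) < 2) abort("need at least 2 pre-stress values")
  thr <- mean(pre_values) + k_sd * sd(pre_values)
  structure(sum(post_values > thr) / length(post_values), threshold = thr)
}

#' Per-cell fold change in expression
#'
#' Ratio of the mean readout over a post-stress plateau window to the mean
#' over a pre-stress window. A pre-stress mean of exactly zero yields `NA`
#' with `undefined = TRUE` (no pseudo-counts are applied).
#'
#' @inheritParams activation_times
#' @param pre_window Window (min) ending at `stress_time` whose mean is the
#'   unstressed level.
#' @param post_window Window (min) ending at the last frame whose mean is the
#'   stressed plateau level.
#' @return A tibble per cell: `cell_id`, `pre_mean`, `post_mean`,
#'   `fold_change`, `undefined`.
#' @export
fold_change <- function(data, value, stress_time, pre_window = 100,
                        post_window = 100) {
  val <- enquo(value)
  data %>%
    mutate(.value = eval_tidy(val, data)) %>%
    group_by(.data$cell_id) %>%
    summarise(
      pre_mean = mean(.data$.value[.data$time_min < stress_time &
                                     .data$time_min >= stress_time - pre_window]),
      post_mean = mean(.data$.value[.data$time_min >
                                      max(.data$time_min) - post_window]),
      .groups = "drop"
    ) %>%
    mutate(undefined = .data$pre_mean == 0,
           fold_change = ifelse(.data$undefined, NA_real_,
                                .data$post_mean / .data$pre_mean))
}

#' Coefficient of variation
#'
#' Sample standard deviation (denominator `N - 1`) divided by the mean.
#'
#' @param values Numeric vector, length >= 2, with non-zero mean.
#' @return The CV.
#' @examples
#' coefficient_of_variation(c(5, 15)) # 0.7071
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) abort("need at least 2 values")
  m <- mean(values)
  if (m == 0) abort("coefficient of variation undefined for zero mean")
  sd(values) / m
}

#' Instantaneous elongation rates from cell lengths
#'
#' Per-frame growth rate `(log len[i+1] - log len[i]) / dt` computed within a
#' cell cycle only: frame pairs spanning a division (a change in `cycle`)
#' yield no rate.
#'
#' @param data Trace table with `cell_id`, `time_min`, a length column
#'   `length_um` (> 0) and a `cycle` column identifying the cell cycle each
#'   frame belongs to.
#' @return A tibble `cell_id`, `time_min` (left frame of each pair), `cycle`,
#'   `growth_rate` (1/min).
#' @export
instantaneous_growth_rate <- function(data) {
  stopifnot(all(c("cell_id", "time_min", "length_um", "cycle") %in% names(data)))
  if (any(data$length_um <= 0, na.rm = TRUE))
    abort("cell lengths must be positive")
  data %>%
    arrange(.data$cell_id, .data$time_min) %>%
    group_by(.data$cell_id) %>%
    mutate(growth_rate = (log(dplyr::lead(.data$length_um)) -
                            log(.data$length_um)) /
             (dplyr::lead(.data$time_min) - .data$time_min),
           .same_cycle = dplyr::lead(.data$cycle) == .data$cycle) %>%
    ungroup() %>%
    filter(!is.na(.data$growth_rate), .data$.same_cycle) %>%
    select("cell_id", "time_min", "cycle", "growth_rate")
}

# centred Gaussian kernel smoother on a uniform grid; bandwidth in frames
gaussian_smooth <- function(x, bandwidth = 2) {
  n <- length(x)
  if (n == 1 || bandwidth <= 0) return(x)
  half <- max(1L, ceiling(3 * bandwidth))
  w <- dnorm(seq(-half, half), sd = bandwidth)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    ww <- w[(lo - i + half + 1):(hi - i + half + 1)]
    out[i] <- sum(x[lo:hi] * ww) / sum(ww)
  }
  out
}

#' Remove overshooting ("sick") cells by width
#'
#' Cells that overshoot their post-stress plateau are wider than healthy
#' cells. Each cell's width trace is smoothed with a Gaussian kernel
#' (default bandwidth 2 frames) and its maximum is compared against the
#' pooled pre-stress width mean plus `k_sd` standard deviations; traces above
#' the threshold are removed.
#'
#' @param data Trace table with `cell_id`, `time_min`, `width_um`.
#' @param stress_time Time of stress addition (min); frames before it define
#'   the pooled pre-stress width distribution.
#' @param k_sd Threshold stringency (default 6).
#' @param bandwidth Gaussian kernel bandwidth in frames (default 2).
#' @return A list with `kept` and `removed` (the partitioned trace tables),
#'   `removed_ids`, and the `threshold` used.
#' @export
filter_overshooting <- function(data, stress_time, k_sd = 6, bandwidth = 2) {
  stopifnot(all(c("cell_id", "time_min") %in% names(data)))
  if (!"width_um" %in% names(data)) abort("width channel 'width_um' missing")
  pre <- data$width_um[data$time_min < stress_time]
  if (length(pre) < 2) abort("no pre-stress frames to set the width threshold")
  thr <- mean(pre) + k_sd * sd(pre)
  peak <- data %>%
    arrange(.data$cell_id, .data$time_min) %>%
    group_by(.data$cell_id) %>%
    summarise(max_width = max(gaussian_smooth(.data$width_um, bandwidth)),
              .groups = "drop")
  bad <- peak$cell_id[peak$max_width > thr]
  list(kept = filter(data, !.data$cell_id %in% bad),
       removed = filter(data, .data$cell_id %in% bad),
       removed_ids = bad, threshold = thr)
}

#' Does the pre-stress level predict the activation time?
#'
#' Splits cells into high/low pre-stress expression groups at the pre-stress
#' mean plus `k_sd` standard deviations (default 1) and compares the two
#' groups' activation-time distributions with a two-sample Kolmogorov-Smirnov
#' test (two-sided; exact p-value where feasible). The null is rejected at
#' p < 0.05. Censored cells carry no activation time and are excluded from
#' the test.
#'
#' @param summaries Output of [activation_times()] (must retain
#'   `prestress_mean`).
#' @param k_sd Split stringency in standard deviations (default 1).
#' @return A list: `n_high`, `n_low`, `D`, `p_value`, `reject`,
#'   `mean_time_high`, `mean_time_low`, `threshold`; `computable = FALSE`
#'   when either group is empty.
#' @export
compare_activation_by_prestress <- function(summaries, k_sd = 1) {
  stopifnot(all(c("prestress_mean", "activation_time", "censored") %in%
                  names(summaries)))
  thr <- mean(summaries$prestress_mean) + k_sd * sd(summaries$prestress_mean)
  ok <- !summaries$censored
  hi <- summaries$activation_time[ok & summaries$prestress_mean > thr]
  lo <- summaries$activation_time[ok & summaries$prestress_mean <= thr]
  if (length(hi) == 0 || length(lo) == 0)
    return(list(computable = FALSE, n_high = length(hi), n_low = length(lo),
                threshold = thr))
  ks <- suppressWarnings(ks.test(hi, lo))
  list(computable = TRUE, n_high = length(hi), n_low = length(lo),
       D = unname(ks$statistic), p_value = ks$p.value,
       reject = ks$p.value < 0.05,
       mean_time_high = mean(hi), mean_time_low = mean(lo), threshold = thr)
}
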