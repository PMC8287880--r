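#' Configuration of the synthetic mother-machine generator
#'
#' Collects the knobs of the synthetic single-cell trace generator. The
#' defaults emulate the imaging conditions of the mother-machine experiments
#' the model mirrors: frames every 10 min, a ~15 min reporter maturation
#' time, a cell-cycle time of 51 +/- 13 min, multiplicative log-normal
#' measurement noise, and a width channel whose inflation marks "sick" cells.
#'
#' @param frame_interval Imaging cadence (min).
#' @param maturation_time Reporter maturation time constant (min); the
#'   immature-to-mature conversion is first order with rate
#'   `1/maturation_time`. Zero disables the maturation stage.
#' @param division_time_mean,division_time_sd Cell-cycle time (min); per-cell
#'   elongation rates are `log(2)` divided by a draw from this distribution
#'   (truncated below at 20 min).
#' @param measurement_noise Standard deviation of the multiplicative
#'   log-normal measurement noise on fluorescence (0 = noiseless). The noise
#'   factor has mean 1.
#' @param width_mean,width_sd Baseline cell width (um) and its per-frame
#'   noise.
#' @param sick_fraction Fraction of cells that turn "sick" (wide) after
#'   stress.
#' @param sick_width_factor Width inflation factor of sick cells.
#' @param prestress_correlation Coupling between a cell's pre-stress reporter
#'   level and its switch rate in the programmed generator mode: the
#'   per-cell switching rate is multiplied by
#'   `exp(prestress_correlation * z)` where `z` is the z-score of the cell's
#'   log pre-stress level. Zero decouples them.
#' @param survival_rule Function mapping a reporter level at lethal-stress
#'   onset to a survival probability in `[0, 1]`. There is no measured
#'   dose-survival curve for this pathway, so the rule is a free modelling
#'   knob; the default is a soft threshold increasing in the reporter level.
#' @param birth_length Cell length at birth (um).
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(frame_interval = 10, maturation_time = 15,
                             division_time_mean = 51, division_time_sd = 13,
                             measurement_noise = 0.05,
                             width_mean = 1, width_sd = 0.05,
                             sick_fraction = 0, sick_width_factor = 1.5,
                             prestress_correlation = 0,
                             survival_rule = function(yfp)
                               0.02 + 0.38 * stats::plogis((yfp - 50) / 10),
                             birth_length = 2) {
  cfg <- list(frame_interval = frame_interval,
              maturation_time = maturation_time,
              division_time_mean = division_time_mean,
              division_time_sd = division_time_sd,
              measurement_noise = measurement_noise,
              width_mean = width_mean, width_sd = width_sd,
              sick_fraction = sick_fraction,
              sick_width_factor = sick_width_factor,
              prestress_correlation = prestress_correlation,
              survival_rule = survival_rule,
              birth_length = birth_length)
  num <- setdiff(names(cfg), "survival_rule")
  for (nm in num)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] < 0)
      abort(paste0("generator_config field '", nm,
                   "' must be a single non-negative number"))
  if (cfg$sick_fraction > 1) abort("sick_fraction must be in [0, 1]")
  if (!is.function(cfg$survival_rule))
    abort("survival_rule must be a function")
  structure(cfg, class = "generator_config")
}

# exact update of the two-stage (immature -> mature) linear reporter cascade
# over one interval of constant production p
reporter_step <- function(Y, M, p, h, k_m, k_dil) {
  if (k_m == 0) { # no maturation stage: production feeds the mature pool
    Mn <- p / k_dil + (M - p / k_dil) * exp(-k_dil * h)
    return(c(0, Mn))
  }
  a <- k_m + k_dil
  b <- k_dil
  Yn <- p / a + (Y - p / a) * exp(-a * h)
  Mn <- M * exp(-b * h) +
    k_m * ((p / a) * (1 - exp(-b * h)) / b +
             (Y - p / a) * (exp(-b * h) - exp(-a * h)) / (a - b))
  c(Yn, Mn)
}

#' Synthetic fluorescent-reporter trace from a model trajectory
#'
#' Converts a simulated trajectory of the circuit into a transcriptional
#' reporter trace: the reporter is produced at a rate proportional to the
#' Hill production term evaluated on the trajectory's free sigma-V (promoter
#' activity, not free sigma-V itself), matures with a first-order delay, is
#' diluted at `k_deg`, is sampled on the imaging frames and is corrupted by
#' multiplicative log-normal noise. Deterministic for a fixed seed.
#'
#' @param trajectory A [simulate_ssa()] / [simulate_cle()] trajectory
#'   (sampled at most every `frame_interval` minutes).
#' @param config A [generator_config()].
#' @param params The [circuit_params()] whose Hill term and dilution rate
#'   drive the reporter.
#' @param seed Integer seed for the measurement noise.
#' @return A tibble `frame`, `time_min`, `yfp` (noisy), `yfp_true`
#'   (noiseless).
#' @export
generate_reporter_trace <- function(trajectory, config = generator_config(),
                                    params = circuit_params(), seed = 1L) {
  stopifnot(is.data.frame(trajectory),
            all(c("time_min", "sigv") %in% names(trajectory)))
  dt_traj <- min(diff(trajectory$time_min))
  if (dt_traj > config$frame_interval + 1e-9)
    abort("trajectory must be sampled at least as finely as frame_interval")
  p <- hill_production_rate(trajectory$sigv, params)
  k_m <- if (config$maturation_time > 0) 1 / config$maturation_time else 0
  k_dil <- max(params$k_deg, 1e-12)
  n <- length(p)
  Y <- numeric(n); M <- numeric(n)
  # start the cascade at quasi-steady state of the initial production rate
  if (k_m > 0) {
    Y[1] <- p[1] / (k_m + k_dil)
    M[1] <- k_m * Y[1] / k_dil
  } else M[1] <- p[1] / k_dil
  for (i in seq_len(n - 1)) {
    h <- trajectory$time_min[i + 1] - trajectory$time_min[i]
    ym <- reporter_step(Y[i], M[i], p[i], h, k_m, k_dil)
    Y[i + 1] <- ym[1]; M[i + 1] <- ym[2]
  }
  frames <- which(abs(trajectory$time_min %% config$frame_interval) < 1e-9 |
                    abs(trajectory$time_min %% config$frame_interval -
                          config$frame_interval) < 1e-9)
  tt <- trajectory$time_min[frames]
  true <- M[frames]
  s <- config$measurement_noise
  noise <- if (s > 0)
    withr::with_seed(as.integer(seed),
                     rlnorm(length(true), meanlog = -s^2 / 2, sdlog = s))
  else rep(1, length(true))
  tibble(frame = seq_along(tt), time_min = tt,
         yfp = true * noise, yfp_true = true)
}

# per-cell length/width/cycle channels on the frame grid
grow_channels <- function(times, stress_time, lambda, sick, config, seed) {
  withr::with_seed(as.integer(seed), {
    cycle_len <- log(2) / lambda
    n <- length(times)
    cycle <- floor((times - times[1]) / cycle_len)
    phase <- (times - times[1]) - cycle * cycle_len
    len <- config$birth_length * exp(lambda * phase)
    width <- config$width_mean + rnorm(n, 0, config$width_sd)
    if (sick) {
      post <- times >= stress_time
      ramp <- pmin(1, (times[post] - stress_time) / 50)
      width[post] <- width[post] +
        config$width_mean * (config$sick_width_factor - 1) * ramp
    }
    tibble(cycle = cycle + 1, length_um = len, width_um = width)
  })
}

#' Synthetic mother-machine ensemble with known ground truth
#'
#' Generates `N` single-cell reporter traces shaped like mother-machine data
#' (frames, reporter maturation and noise, exponential length growth with
#' divisions, width channel with an optional "sick" subpopulation), together
#' with the ground truth needed to test every trace statistic.
#'
#' Two modes:
#' * `"ssa"` — each cell is an exact stochastic simulation of the circuit
#'   under `protocol`; the reporter follows the cell's promoter activity.
#' * `"programmed"` — each cell's noiseless reporter is a logistic step whose
#'   centre (the programmed switch time) is drawn from an exponential delay
#'   after stress; the per-cell switching rate is coupled to the cell's
#'   pre-stress baseline via `prestress_correlation`. This mode gives exact,
#'   independently-known switch times.
#'
#' The per-cell ground-truth `switch_time` is defined, in both modes, as the
#' half-maximum crossing of the *noiseless* reporter trace (computed with
#' [activation_times()] on `yfp_true`), so estimator tests measure noise
#' robustness rather than the physical maturation lag. In `"ssa"` mode the
#' half-max crossing of free sigma-V itself is also recorded
#' (`switch_time_sigv`); in `"programmed"` mode the programmed logistic
#' centre is recorded (`programmed_switch`).
#'
#' @param config A [generator_config()].
#' @param N Number of cells.
#' @param protocol Stress protocol (a single step; the first segment with
#'   `L > 0` defines the stress time).
#' @param network Circuit network driving `"ssa"` mode.
#' @param mode `"ssa"` or `"programmed"`.
#' @param seed Integer seed; every draw in the generator derives from it.
#' @param final_window Trailing window defining the "final level" in the
#'   ground-truth half-max rule (min).
#' @return A list with `traces` (tibble: `cell_id`, `frame`, `time_min`,
#'   `yfp`, `yfp_true`, `rfp`, `length_um`, `width_um`, `cycle`) and `truth`
#'   (tibble: `cell_id`, `switch_time`, `censored`, `growth_rate`, `sick`,
#'   `prestress_mean`, plus the mode-specific columns above).
#' @export
generate_mother_machine_ensemble <- function(config = generator_config(),
                                             N = 50,
                                             protocol = step_protocol(500, 1, 1500),
                                             network = build_network(),
                                             mode = c("ssa", "programmed"),
                                             seed = 1L,
                                             final_window = 100) {
  mode <- match.arg(mode)
  stopifnot(N >= 1)
  stress_time <- protocol$start[which(protocol$L > 0)[1]]
  if (is.na(stress_time)) abort("protocol has no stress phase")
  duration <- protocol_duration(protocol)
  seeds <- derive_seeds(seed, 3L * N + 1L)
  times <- seq(0, duration, by = config$frame_interval)

  cell_seed <- function(i, k) seeds[3L * (i - 1L) + k]

  sick <- withr::with_seed(seeds[3L * N + 1L],
                           runif(N) < config$sick_fraction)
  lambda <- withr::with_seed(seeds[3L * N + 1L] %% 1000000L + 1L, {
    tdiv <- pmax(rnorm(N, config$division_time_mean, config$division_time_sd),
                 20)
    log(2) / tdiv
  })

  traces <- vector("list", N)
  sigv_traj <- vector("list", N)
  prog_centre <- rep(NA_real_, N)

  if (mode == "programmed") {
    prog <- withr::with_seed(seeds[1], {
      base <- rlnorm(N, meanlog = log(2), sdlog = 0.4)
      z <- as.numeric(scale(log(base)))
      rate <- 0.01 * exp(config$prestress_correlation * z)
      list(base = base, delay = stats::rexp(N, rate))
    })
    prog_centre <- stress_time + prog$delay
  }

  for (i in seq_len(N)) {
    if (mode == "ssa") {
      tr <- simulate_ssa(network, protocol,
                         sample_interval = config$frame_interval,
                         seed = cell_seed(i, 1))
      sigv_traj[[i]] <- tr
      rep_tr <- generate_reporter_trace(tr, config, network$params,
                                        seed = cell_seed(i, 2))
    } else {
      w <- config$frame_interval # rise width of the logistic switch
      true <- prog$base[i] +
        (100 - prog$base[i]) / (1 + exp(-(times - prog_centre[i]) / w))
      s <- config$measurement_noise
      noise <- if (s > 0)
        withr::with_seed(cell_seed(i, 2),
                         rlnorm(length(true), -s^2 / 2, s))
      else rep(1, length(true))
      rep_tr <- tibble(frame = seq_along(times), time_min = times,
                       yfp = true * noise, yfp_true = true)
    }
    gc_ch <- grow_channels(rep_tr$time_min, stress_time, lambda[i], sick[i],
                           config, cell_seed(i, 3))
    rfp_noise <- if (config$measurement_noise > 0)
      withr::with_seed(cell_seed(i, 3) %% 1000000L + 2L,
                       rlnorm(nrow(rep_tr), -config$measurement_noise^2 / 2,
                              config$measurement_noise))
    else rep(1, nrow(rep_tr))
    traces[[i]] <- bind_rows(tibble(
      cell_id = i, frame = rep_tr$frame, time_min = rep_tr$time_min,
      yfp = rep_tr$yfp, yfp_true = rep_tr$yfp_true,
      rfp = 50 * rfp_noise,
      length_um = gc_ch$length_um, width_um = gc_ch$width_um,
      cycle = gc_ch$cycle))
  }
  traces <- bind_rows(traces)

  truth <- activation_times(
    mutate(traces, .noiseless = .data$yfp_true),
    .noiseless, stress_time = stress_time, final_window = final_window) %>%
    select("cell_id", switch_time = "activation_time", "censored",
           "prestress_mean")
  truth$growth_rate <- lambda
  truth$sick <- sick
  if (mode == "ssa") {
    sig_all <- bind_rows(lapply(seq_len(N), function(i) {
      out <- as_tibble(sigv_traj[[i]])[, c("time_min", "sigv")]
      out$cell_id <- i
      out
    }))
    sig_at <- activation_times(sig_all, .data$sigv, stress_time = stress_time,
                               final_window = final_window)
    truth$switch_time_sigv <- sig_at$activation_time[match(truth$cell_id,
                                                           sig_at$cell_id)]
  } else {
    truth$programmed_switch <- prog_centre - stress_time
  }
  list(traces = traces, truth = truth, config = config,
       stress_time = stress_time, mode = mode)
}

#' Synthetic priming-experiment lineage forest
#'
#' Builds channel-wise lineage forests emulating the priming-survival
#' experiment: cells carry a reporter level at the moment the lethal stress
#' hits, survival is Bernoulli with probability `survival_rule(level)`,
#' survivors keep dividing to the end of the movie (so descendant lineages
#' exist and the longest-lineage-only rule is exercised), dying cells end
#' with a death event, and a configurable fraction of cells below the top
#' three ranks is washed out of the channel after the stress. Cells that left
#' the channel before the stress provide the positions from which the channel
#' end is estimated.
#'
#' @param config A [generator_config()]; `survival_rule` maps the reporter
#'   level at lethal onset to a survival probability.
#' @param channels Number of mother-machine channels.
#' @param cells_per_channel Cells present in each channel at the lethal
#'   stress (>= 3).
#' @param assay_start Time of lethal-stress addition (min).
#' @param assay_end End of the movie (min); the published protocol scores
#'   survival 280 min after the lethal stress.
#' @param channel_length Channel length (um); the open end is at this
#'   position, the dead end at 0.
#' @param washout_prob Probability that a cell of rank > 3 leaves the channel
#'   after the stress instead of being scored.
#' @param activated_fraction Fraction of cells whose priming response put
#'   their reporter in the high (primed) state at lethal onset.
#' @param seed Integer seed.
#' @return A list with `forest` (see [survival_fraction()]) and `truth`
#'   (per scored cell: `cell_id`, `channel`, `rank_at_assay`,
#'   `reporter_at_lethal`, `survived`; washed-out cells have `survived = NA`).
#' @export
generate_priming_lineages <- function(config = generator_config(),
                                      channels = 30, cells_per_channel = 6,
                                      assay_start = 1000,
                                      assay_end = 1280,
                                      channel_length = 25,
                                      washout_prob = 0.15,
                                      activated_fraction = 0.3,
                                      seed = 1L) {
  stopifnot(cells_per_channel >= 3, channels >= 1, assay_end > assay_start)
  rule <- config$survival_rule
  withr::with_seed(as.integer(seed), {
    rows <- list()
    truth <- list()
    next_id <- 1L
    new_id <- function() {
      id <- sprintf("c%06d", next_id)
      next_id <<- next_id + 1L
      id
    }
    for (ch in seq_len(channels)) {
      # pre-stress channel exits: calibrate the channel-end estimate
      for (j in 1:15) {
        rows[[length(rows) + 1]] <- tibble(
          cell_id = new_id(), channel = ch, parent_id = NA_character_,
          birth_min = runif(1, 0, assay_start - 200),
          end_min = runif(1, assay_start - 900, assay_start - 10),
          end_cause = "left_channel", rank_at_assay = NA_real_,
          last_pos = rnorm(1, channel_length, 0.3),
          reporter_at_lethal = NA_real_)
      }
      for (rank in seq_len(cells_per_channel)) {
        id <- new_id()
        pos <- rank * 2.5
        primed <- runif(1) < activated_fraction
        yfp <- if (primed) rlnorm(1, log(80), 0.25) else rlnorm(1, log(20), 0.25)
        washed <- rank > 3 && runif(1) < washout_prob
        if (washed) {
          rows[[length(rows) + 1]] <- tibble(
            cell_id = id, channel = ch, parent_id = NA_character_,
            birth_min = assay_start - runif(1, 10, 60),
            end_min = assay_start + runif(1, 30, 200),
            end_cause = "left_channel", rank_at_assay = rank,
            last_pos = rnorm(1, channel_length, 0.3),
            reporter_at_lethal = yfp)
          truth[[length(truth) + 1]] <- tibble(
            cell_id = id, channel = ch, rank_at_assay = rank,
            reporter_at_lethal = yfp, survived = NA)
          next
        }
        survives <- runif(1) < rule(yfp)
        if (!survives) {
          rows[[length(rows) + 1]] <- tibble(
            cell_id = id, channel = ch, parent_id = NA_character_,
            birth_min = assay_start - runif(1, 10, 60),
            end_min = assay_start + runif(1, 10, 60),
            end_cause = "death", rank_at_assay = rank,
            last_pos = pos, reporter_at_lethal = yfp)
        } else {
          # surviving lineage: division chain to the end of the movie, with
          # one dying sibling per division
          rows[[length(rows) + 1]] <- tibble(
            cell_id = id, channel = ch, parent_id = NA_character_,
            birth_min = assay_start - runif(1, 10, 60),
            end_min = assay_start + config$division_time_mean,
            end_cause = "division", rank_at_assay = rank,
            last_pos = pos, reporter_at_lethal = yfp)
          parent <- id
          t <- assay_start + config$division_time_mean
          while (t < assay_end) {
            keep <- new_id(); sib <- new_id()
            t_next <- t + config$division_time_mean
            rows[[length(rows) + 1]] <- tibble(
              cell_id = keep, channel = ch, parent_id = parent,
              birth_min = t,
              end_min = if (t_next < assay_end) t_next else assay_end,
              end_cause = if (t_next < assay_end) "division" else "movie_end",
              rank_at_assay = NA_real_, last_pos = pos,
              reporter_at_lethal = NA_real_)
            rows[[length(rows) + 1]] <- tibble(
              cell_id = sib, channel = ch, parent_id = parent,
              birth_min = t, end_min = min(t + 20, assay_end - 1),
              end_cause = "death", rank_at_assay = NA_real_,
              last_pos = pos + 2.5, reporter_at_lethal = NA_real_)
            parent <- keep
            t <- t_next
          }
        }
        truth[[length(truth) + 1]] <- tibble(
          cell_id = id, channel = ch, rank_at_assay = rank,
          reporter_at_lethal = yfp,
          survived = if (washed) NA else survives)
      }
    }
    list(forest = bind_rows(rows), truth = bind_rows(truth), config = config,
         assay_start = assay_start, assay_end = assay_end)
  })
}
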