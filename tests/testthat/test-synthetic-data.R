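test_that("reporter of an inactive circuit is flat at the leak steady state", {
  params <- circuit_params()
  traj <- tibble::tibble(time_min = seq(0, 500, 10), sigv = 0)
  # without a maturation stage the plateau is exactly v0/k_deg
  tr0 <- generate_reporter_trace(traj,
                                 generator_config(measurement_noise = 0,
                                                  maturation_time = 0),
                                 params)
  expect_equal(unique(round(tr0$yfp, 8)), params$v0 / params$k_deg)
  # with maturation, dilution of the immature pool scales the plateau by
  # k_m / (k_m + k_deg); the trace is still flat and proportional to v0/k_deg
  tr <- generate_reporter_trace(traj, generator_config(measurement_noise = 0),
                                params)
  k_m <- 1 / 15
  expect_equal(unique(round(tr$yfp, 8)),
               round(params$v0 / params$k_deg * k_m / (k_m + params$k_deg), 8))
})

test_that("reporter lag grows with maturation time and vanishes without it", {
  params <- circuit_params()
  times <- seq(0, 1000, 5)
  traj <- tibble::tibble(time_min = times,
                         sigv = ifelse(times >= 300, 300, 0))
  half_rise <- function(maturation) {
    cfg <- generator_config(maturation_time = maturation,
                            measurement_noise = 0, frame_interval = 5)
    tr <- generate_reporter_trace(traj, cfg, params)
    plateau <- max(tr$yfp)
    base <- tr$yfp[1]
    tr$time_min[which(tr$yfp >= base + (plateau - base) / 2)[1]]
  }
  lag0 <- half_rise(0)
  lag15 <- half_rise(15)
  lag60 <- half_rise(60)
  expect_true(lag0 < lag15 & lag15 < lag60)
})

test_that("the reporter cascade matches an independent ODE integration", {
  params <- circuit_params()
  times <- seq(0, 400, 10)
  traj <- tibble::tibble(time_min = times,
                         sigv = ifelse(times >= 100, 250, 0))
  cfg <- generator_config(maturation_time = 15, measurement_noise = 0)
  tr <- generate_reporter_trace(traj, cfg, params)
  k_m <- 1 / 15
  k_dil <- params$k_deg
  prod_at <- stats::approxfun(times, hill_production_rate(traj$sigv, params),
                              method = "constant", rule = 2)
  rhs <- function(t, y, parms)
    list(c(prod_at(t) - (k_m + k_dil) * y[1], k_m * y[1] - k_dil * y[2]))
  y0 <- c(hill_production_rate(0, params) / (k_m + k_dil), 0)
  y0[2] <- k_m * y0[1] / k_dil
  sol <- deSolve::lsoda(y0, times, rhs, rtol = 1e-10, atol = 1e-10)
  expect_equal(tr$yfp, sol[, 3], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("noiseless zero-maturation traces recover truth exactly", {
  cfg <- generator_config(measurement_noise = 0, maturation_time = 0)
  gen <- generate_mother_machine_ensemble(cfg, N = 30,
                                          protocol = step_protocol(300, 1, 1200),
                                          mode = "programmed", seed = 40)
  rec <- activation_times(gen$traces, yfp, stress_time = 300)
  j <- dplyr::inner_join(rec, gen$truth, by = "cell_id",
                         suffix = c("", "_true"))
  ok <- !j$censored & !j$censored_true
  expect_gt(sum(ok), 20)
  expect_equal(j$activation_time[ok], j$switch_time[ok])
})

test_that("noisy traces recover switch times within one frame", {
  cfg <- generator_config(measurement_noise = 0.05, maturation_time = 0)
  gen <- generate_mother_machine_ensemble(cfg, N = 100,
                                          protocol = step_protocol(300, 1, 1500),
                                          mode = "programmed", seed = 41)
  rec <- activation_times(gen$traces, yfp, stress_time = 300)
  j <- dplyr::inner_join(rec, gen$truth, by = "cell_id",
                         suffix = c("", "_true"))
  ok <- !j$censored & !j$censored_true
  hit <- abs(j$activation_time[ok] - j$switch_time[ok]) <=
    cfg$frame_interval
  expect_gte(mean(hit), 0.95)
})

test_that("generated lengths reproduce the programmed growth rates exactly", {
  cfg <- generator_config(measurement_noise = 0)
  gen <- generate_mother_machine_ensemble(cfg, N = 20,
                                          protocol = step_protocol(200, 1, 800),
                                          mode = "programmed", seed = 42)
  gr <- instantaneous_growth_rate(gen$traces)
  per_cell <- dplyr::summarise(dplyr::group_by(gr, cell_id),
                               lo = min(growth_rate), hi = max(growth_rate),
                               .groups = "drop")
  j <- dplyr::inner_join(per_cell, gen$truth, by = "cell_id")
  expect_equal(j$lo, j$growth_rate, tolerance = 1e-12)
  expect_equal(j$hi, j$growth_rate, tolerance = 1e-12)
})

test_that("the sick fraction is recovered by the width filter", {
  cfg <- generator_config(sick_fraction = 0.2, measurement_noise = 0.05)
  gen <- generate_mother_machine_ensemble(cfg, N = 120,
                                          protocol = step_protocol(300, 1, 900),
                                          mode = "programmed", seed = 43)
  res <- filter_overshooting(gen$traces, stress_time = 300)
  expect_setequal(res$removed_ids, gen$truth$cell_id[gen$truth$sick])
  # binomial 3-sigma band around the configured fraction
  phat <- length(res$removed_ids) / 120
  expect_lt(abs(phat - 0.2), 3 * sqrt(0.2 * 0.8 / 120))
})

test_that("generated datasets are reproducible from config + seed", {
  cfg <- generator_config(sick_fraction = 0.1)
  g1 <- generate_mother_machine_ensemble(cfg, N = 10, mode = "programmed",
                                         seed = 44)
  g2 <- generate_mother_machine_ensemble(cfg, N = 10, mode = "programmed",
                                         seed = 44)
  expect_identical(g1$traces, g2$traces)
  expect_identical(g1$truth, g2$truth)
  p1 <- generate_priming_lineages(generator_config(), channels = 5, seed = 45)
  p2 <- generate_priming_lineages(generator_config(), channels = 5, seed = 45)
  expect_identical(p1$forest, p2$forest)
})

test_that("ssa-mode traces carry the circuit's activation signature", {
  cfg <- generator_config(measurement_noise = 0.05)
  gen <- generate_mother_machine_ensemble(cfg, N = 12,
                                          protocol = step_protocol(500, 2, 1600),
                                          seed = 46)
  rec <- activation_times(gen$traces, yfp, stress_time = 500)
  # most cells respond to a strong stress
  expect_gt(sum(!rec$censored), 8)
  # the reporter switch follows the sigma-V switch with a positive lag
  j <- dplyr::inner_join(rec, gen$truth, by = "cell_id",
                         suffix = c("", "_true"))
  ok <- !j$censored & !is.na(j$switch_time_sigv)
  expect_gte(median(j$activation_time[ok] - j$switch_time_sigv[ok]), 0)
})
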