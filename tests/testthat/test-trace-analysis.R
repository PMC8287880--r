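test_that("activation time is the half-max crossing after stress", {
  tr <- step_trace(switch_at = 100) # steps 0 -> 100 at t = 100
  a <- activation_times(tr, yfp, stress_time = 60, final_window = 100)
  expect_equal(a$activation_time, 40)
  expect_equal(a$half_max, 50)
  expect_false(a$censored)
  # flat zero trace is censored
  flat <- tibble::tibble(cell_id = 1, time_min = seq(0, 300, 10), yfp = 0)
  expect_true(activation_times(flat, yfp, stress_time = 60)$censored)
  expect_error(activation_times(tr, yfp, stress_time = 500), "before")
})

test_that("activation time is gain-invariant and time-shift equivariant", {
  tr <- step_trace(switch_at = 120)
  base <- activation_times(tr, yfp, stress_time = 60)$activation_time
  gained <- dplyr::mutate(tr, yfp = 7.3 * yfp)
  expect_equal(activation_times(gained, yfp, stress_time = 60)$activation_time,
               base)
  shifted <- dplyr::mutate(tr, time_min = time_min + 50)
  expect_equal(activation_times(shifted, yfp,
                                stress_time = 110)$activation_time, base)
})

test_that("cumulative activation curves count censored cells in denominators", {
  s <- tibble::tibble(cell_id = 1:3, activation_time = c(10, 20, 30),
                      censored = FALSE)
  expect_equal(cumulative_activation_curve(s, c(15, 25, 35))$fraction,
               c(1, 2, 3) / 3)
  s4 <- tibble::tibble(cell_id = 1:4,
                       activation_time = c(10, 10, 30, NA),
                       censored = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(cumulative_activation_curve(s4, 10)$fraction, 0.5)
  all_cens <- tibble::tibble(cell_id = 1:3, activation_time = NA_real_,
                             censored = TRUE)
  expect_true(all(cumulative_activation_curve(all_cens,
                                              c(0, 100, 1e6))$fraction == 0))
  # monotone, bounded by 1; reaches 1 iff nothing censored
  expect_false(is.unsorted(cumulative_activation_curve(s4, 0:40)$fraction))
  expect_equal(max(cumulative_activation_curve(s, c(30, 1e9))$fraction), 1)
  expect_lt(max(cumulative_activation_curve(s4, 1e9)$fraction), 1)
})

test_that("snapshot activation fraction uses the mean + k*sd threshold", {
  f <- fraction_activated_snapshot(c(9, 10, 11), c(10, 17, 10, 17))
  expect_equal(as.numeric(f), 0.5)
  expect_equal(attr(f, "threshold"), 10 + 6 * 1)
  expect_equal(as.numeric(
    fraction_activated_snapshot(c(9, 10, 11), c(10, 12, 14))), 0)
  # zero variance + post equal to the mean: strict inequality gives 0
  expect_equal(as.numeric(fraction_activated_snapshot(c(5, 5, 5), c(5, 5))), 0)
  # same distribution: the 6-sd tail is essentially empty
  set.seed(1)
  pre <- rnorm(1000, 100, 10)
  post <- rnorm(1000, 100, 10)
  expect_lt(as.numeric(fraction_activated_snapshot(pre, post)), 0.01)
  # k_sd -> Inf excludes everything; k_sd = 0 thresholds at the pre mean
  expect_equal(as.numeric(fraction_activated_snapshot(pre, post, 1e9)), 0)
  expect_equal(as.numeric(fraction_activated_snapshot(pre, post, 0)),
               mean(post > mean(pre)))
  expect_error(fraction_activated_snapshot(5, c(1, 2)), "at least 2")
})

test_that("fold change is the post/pre window ratio without pseudo-counts", {
  tr <- tibble::tibble(cell_id = 1, time_min = seq(0, 300, 10),
                       yfp = ifelse(seq(0, 300, 10) < 150, 10, 100))
  fc <- fold_change(tr, yfp, stress_time = 150)
  expect_equal(fc$fold_change, 10)
  flat <- tibble::tibble(cell_id = 1, time_min = seq(0, 300, 10), yfp = 4)
  expect_equal(fold_change(flat, yfp, stress_time = 150)$fold_change, 1)
  zero <- tibble::tibble(cell_id = 1, time_min = seq(0, 300, 10),
                         yfp = ifelse(seq(0, 300, 10) < 150, 0, 10))
  fz <- fold_change(zero, yfp, stress_time = 150)
  expect_true(fz$undefined)
  expect_true(is.na(fz$fold_change))
})

test_that("coefficient of variation uses the sample standard deviation", {
  expect_equal(coefficient_of_variation(c(10, 10, 10)), 0)
  expect_equal(coefficient_of_variation(c(5, 15)), sd(c(5, 15)) / 10)
  set.seed(2)
  x <- rnorm(1e4, 100, 20)
  expect_equal(coefficient_of_variation(x), 0.2, tolerance = 0.02)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("growth rates follow the log-length difference within a cycle", {
  tr <- tibble::tibble(cell_id = 1, time_min = seq(0, 40, 10),
                       length_um = c(1, exp(0.5), exp(1), 1, exp(0.5)),
                       cycle = c(1, 1, 1, 2, 2))
  gr <- instantaneous_growth_rate(tr)
  # (log e^0.5 - log 1) / 10 = 0.05/min; the division pair is absent
  expect_equal(nrow(gr), 3)
  expect_equal(gr$growth_rate, c(0.05, 0.05, 0.05))
  expect_false(any(gr$time_min == 20)) # frame pair spanning the division
  const <- tibble::tibble(cell_id = 1, time_min = c(0, 10), length_um = 2,
                          cycle = 1)
  expect_equal(instantaneous_growth_rate(const)$growth_rate, 0)
  bad <- dplyr::mutate(const, length_um = c(2, -1))
  expect_error(instantaneous_growth_rate(bad), "positive")
})

test_that("overshoot filtering removes exactly the wide traces", {
  times <- seq(0, 200, 10)
  mk <- function(id, w) tibble::tibble(cell_id = id, time_min = times,
                                       width_um = w)
  healthy <- dplyr::bind_rows(lapply(1:6, function(i)
    mk(i, 1 + 0.01 * sin(times + i))))
  expect_length(filter_overshooting(healthy,
                                    stress_time = 100)$removed_ids, 0)
  spike <- mk(99, c(rep(1, 15), rep(2, 6))) # late spike far above pre-stress
  both <- dplyr::bind_rows(healthy, spike)
  res <- filter_overshooting(both, stress_time = 100)
  expect_equal(res$removed_ids, 99)
  expect_false(99 %in% res$kept$cell_id)
  expect_true(all(res$removed$cell_id == 99))
  expect_error(filter_overshooting(dplyr::select(healthy, -width_um),
                                   stress_time = 100), "width")
})

test_that("pre-stress level splitting feeds the KS comparison correctly", {
  # a small bright subpopulation far above the mean + 1 sd threshold,
  # activating much earlier: disjoint supports give D = 1 and rejection
  s <- tibble::tibble(cell_id = 1:16,
                      prestress_mean = c(rep(10, 12), rep(100, 4)),
                      activation_time = c(seq(100, 210, by = 10),
                                          10, 11, 12, 13),
                      censored = FALSE)
  res <- compare_activation_by_prestress(s)
  expect_true(res$computable)
  expect_equal(res$n_high, 4)
  expect_equal(res$D, 1) # disjoint supports
  expect_true(res$reject)
  expect_lt(res$mean_time_high, res$mean_time_low)
  # identical distributions in both groups: D = 0, no rejection
  s2 <- tibble::tibble(cell_id = 1:8,
                       prestress_mean = c(rep(0, 6), 100, 100),
                       activation_time = c(rep(c(5, 10), 3), 5, 10),
                       censored = FALSE)
  res2 <- compare_activation_by_prestress(s2)
  expect_equal(res2$D, 0)
  expect_false(res2$reject)
  # empty high group is flagged not computable
  s3 <- dplyr::mutate(s, prestress_mean = 10)
  expect_false(compare_activation_by_prestress(s3)$computable)
})

test_that("built-in pre-stress coupling in the generator is detected", {
  cfg <- generator_config(prestress_correlation = 2, measurement_noise = 0.03,
                          maturation_time = 0)
  gen <- generate_mother_machine_ensemble(cfg, N = 100,
                                          protocol = step_protocol(200, 1, 1400),
                                          mode = "programmed", seed = 14)
  acts <- activation_times(gen$traces, yfp, stress_time = 200)
  res <- compare_activation_by_prestress(acts)
  expect_true(res$computable)
  expect_true(res$reject)
  expect_lt(res$mean_time_high, res$mean_time_low)
})
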