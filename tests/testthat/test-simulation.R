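test_that("a network with no active channel yields a constant trajectory", {
  tr <- simulate_ssa(frozen_network(), constant_protocol(0, 200),
                     init = c(5, 5, 5), seed = 1)
  expect_true(all(tr$sigv == 5 & tr$rsiv == 5 & tr$complex == 5))
  expect_equal(tr$time_min, seq(0, 200, 10))
})

test_that("SSA reproduces the linear death process closed form", {
  net <- pure_death_network(0.01)
  final <- vapply(1:300, function(s) {
    tr <- simulate_ssa(net, constant_protocol(0, 100), sample_interval = 100,
                       init = c(100, 0, 0), seed = s)
    tr$sigv[tr$time_min == 100]
  }, numeric(1))
  expected <- 100 * exp(-1)
  se <- sd(final) / sqrt(length(final))
  expect_lt(abs(mean(final) - expected), 3 * se)
})

test_that("SSA and CLE are exactly reproducible for a fixed seed", {
  net <- build_network()
  prot <- step_protocol(100, 1, 400)
  a <- simulate_ssa(net, prot, seed = 123)
  b <- simulate_ssa(net, prot, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a),
                         as.data.frame(simulate_ssa(net, prot, seed = 124))))
  ca <- simulate_cle(net, prot, dt = 0.001, seed = 9)
  cb <- simulate_cle(net, prot, dt = 0.001, seed = 9)
  expect_identical(as.data.frame(ca), as.data.frame(cb))
})

test_that("ensembles are reproducible and wrap individual runs faithfully", {
  net <- build_network()
  prot <- step_protocol(100, 1, 300)
  e1 <- simulate_ensemble(net, prot, N = 4, base_seed = 5)
  e2 <- simulate_ensemble(net, prot, N = 4, base_seed = 5)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  # N = 1 wraps a single simulate_ssa run with the derived seed
  single <- simulate_ensemble(net, prot, N = 1, base_seed = 5)
  direct <- simulate_ssa(net, prot, seed = attr(single, "seeds")[1])
  expect_equal(single$sigv, direct$sigv)
  # member seeds are distinct
  expect_equal(anyDuplicated(attr(e1, "seeds")), 0)
})

test_that("per-event conservation laws hold along SSA paths", {
  net <- build_network()
  tr <- simulate_ssa(net, step_protocol(100, 1, 300), init = c(0, 0, 0),
                     seed = 77, record_events = TRUE)
  ev <- attr(tr, "events")
  expect_gt(nrow(ev), 100)
  path <- replay_events(net, c(0, 0, 0), ev$channel)
  expect_true(all(path >= 0))
  sig_tot <- path[, "sigv"] + path[, "complex"]
  r_tot <- path[, "rsiv"] + path[, "complex"]
  nm <- net$channels$name[ev$channel]
  d_sig <- diff(sig_tot)
  d_r <- diff(r_tot)
  expect_true(all(d_sig[nm %in% c("binding", "dissociation")] == 0))
  expect_true(all(d_r[nm %in% c("binding", "dissociation")] == 0))
  expect_true(all(d_sig[nm == "cleavage"] == 0))
  expect_true(all(d_r[nm == "cleavage"] == -1))
  # the sampled end state matches the replayed event sequence
  expect_equal(unname(path[nrow(path), ]),
               c(tr$sigv[31], tr$rsiv[31], tr$complex[31]))
})

test_that("SSA ensemble mean converges to the mean-field path with system size", {
  omega <- 50
  net <- build_network(scale_system_size(circuit_params(), omega))
  ss <- steady_state(net, 0)
  init <- round(c(ss$sigv, ss$rsiv, ss$complex))
  prot <- step_protocol(100, 1, 200)
  ens <- simulate_ensemble(net, prot, N = 30, base_seed = 31, init = init)
  mean_path <- dplyr::summarise(dplyr::group_by(ens, time_min),
                                sigv = mean(sigv), .groups = "drop")
  ode <- mean_field_path(net, prot, mean_path$time_min, init = init)
  rel_err <- max(abs(mean_path$sigv - ode$sigv)) / max(ode$sigv)
  expect_lt(rel_err, 0.05)
})

test_that("CLE tracks the deterministic path when noise is suppressed", {
  omega <- 1e4
  net <- build_network(scale_system_size(circuit_params(), omega))
  prot <- step_protocol(100, 1, 300)
  tr <- simulate_cle(net, prot, dt = 0.02, init = c(0, 0, 0), seed = 3)
  ode <- mean_field_path(net, prot, tr$time_min, init = c(0, 0, 0))
  # skip t = 0 where both are zero
  rel <- abs(tr$sigv[-1] - ode$sigv[-1]) / pmax(ode$sigv[-1], 1)
  expect_lt(max(rel), 0.02)
})

test_that("CLE reproduces the linear death process mean", {
  net <- pure_death_network(0.01)
  final <- vapply(1:300, function(s) {
    tr <- simulate_cle(net, constant_protocol(0, 100), dt = 0.05,
                       sample_interval = 100, init = c(100, 0, 0), seed = s)
    tr$sigv[tr$time_min == 100]
  }, numeric(1))
  se <- sd(final) / sqrt(length(final))
  expect_lt(abs(mean(final) - 100 * exp(-1)), 3 * se)
})

test_that("unstressed stationary copy numbers are plausible for a sigma factor", {
  net <- build_network()
  tr <- simulate_ssa(net, constant_protocol(0, 3000), seed = 17)
  keep <- tr$time_min > 500
  total_sigma <- tr$sigv[keep] + tr$complex[keep]
  expect_gt(mean(total_sigma), 1)
  expect_lt(mean(total_sigma), 1e4)
})

test_that("zero total propensity fast-forwards instead of failing", {
  # death-only network that empties, then nothing can fire
  net <- pure_death_network(1)
  tr <- simulate_ssa(net, constant_protocol(0, 100), init = c(3, 0, 0),
                     seed = 2)
  expect_equal(tr$sigv[tr$time_min == 100], 0)
})
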