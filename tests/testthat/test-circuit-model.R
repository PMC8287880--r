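test_that("Hill production rate matches its closed form", {
  p <- circuit_params()
  expect_equal(hill_production_rate(0, p), 0.1)          # leak only
  expect_equal(hill_production_rate(60, p), 0.1 + 2.5 / 2) # half-saturation
  expect_lt(abs(hill_production_rate(1e9, p) - 2.6), 1e-6) # saturation
  # monotone in sigma-V; exact half-saturation identity f(K) - v0 = v/2
  s <- seq(0, 500, length.out = 200)
  expect_true(all(diff(hill_production_rate(s, p)) > 0))
  expect_equal(hill_production_rate(p$K, p) - p$v0, p$v / 2)
  expect_error(hill_production_rate(-1, p), "non-negative")
})

test_that("parameter and variant constructors validate their inputs", {
  expect_error(circuit_params(k_B = -1), "k_B")
  expect_error(circuit_params(n = 0.5), "Hill coefficient")
  expect_error(circuit_variant("feedback_broken"), "magnitude")
  expect_error(circuit_variant("hill_override", 0.5), ">= 1")
  expect_error(circuit_variant("nonsense"), "arg")
  expect_null(circuit_variant("wild_type", magnitude = 3)$magnitude)
})

test_that("wild-type network has the seven expected channels", {
  net <- build_network()
  expect_s3_class(net, "reaction_network")
  expect_equal(nrow(net$channels), 7)
  cleave <- net$channels[net$channels$name == "cleavage", ]
  # cleavage releases sigma-V and degrades RsiV: (+1, 0, -1)
  expect_equal(unlist(cleave[, c("d_sigv", "d_rsiv", "d_complex")],
                      use.names = FALSE), c(1, 0, -1))
  prod <- net$channels[1, ]
  expect_equal(unlist(prod[, c("d_sigv", "d_rsiv", "d_complex")],
                      use.names = FALSE), c(1, 1, 0))
})

test_that("variants add or replace the intended channels", {
  net <- build_network(variant = circuit_variant("second_copy_rsiv"))
  expect_equal(nrow(net$channels), 8)
  extra <- net$channels[8, ]
  expect_equal(unlist(extra[, c("d_sigv", "d_rsiv", "d_complex")],
                      use.names = FALSE), c(0, 1, 0))
  expect_equal(extra$kind, 3) # same Hill propensity as the operon

  fb <- build_network(variant = circuit_variant("feedback_broken", 1))
  expect_equal(nrow(fb$channels), 7)
  # constitutive production is independent of the state
  for (st in list(c(0, 0, 0), c(50, 3, 8), c(1000, 0, 200)))
    expect_equal(propensities(fb, st, 0)$rate[1], 1)

  leak <- build_network(variant = circuit_variant("leak_sigv", 0.2))
  expect_equal(nrow(leak$channels), 8)
  expect_equal(propensities(leak, c(0, 0, 0), 0)$rate[8], 0.2)

  ho <- build_network(circuit_params(),
                      circuit_variant("hill_override", 4))
  expect_equal(ho$channels$c3[1], 4)
})

test_that("propensities follow mass action with printed constants", {
  net <- build_network()
  pr <- propensities(net, c(2, 3, 5), L = 1)
  expect_equal(pr$rate[pr$name == "binding"], 10 * 2 * 3)
  expect_equal(pr$rate[pr$name == "dissociation"], 5 * 5)
  expect_equal(pr$rate[pr$name == "cleavage"], 0.05 * 1 * 5)
  expect_equal(pr$rate[pr$name == "dilution_sigv"], 0.02)
  expect_equal(pr$rate[pr$name == "dilution_rsiv"], 0.03)
  expect_equal(pr$rate[pr$name == "dilution_complex"], 0.05)
  expect_equal(pr$rate[pr$name == "production"],
               0.1 + 2.5 * 4 / (4 + 3600))
  # empty system: only the leak can fire
  pr0 <- propensities(net, c(0, 0, 0), L = 3)
  expect_equal(pr0$rate, c(0.1, 0, 0, 0, 0, 0, 0))
  # no stress, no cleavage
  expect_equal(propensities(net, c(2, 3, 5), 0)$rate[7], 0)
  expect_error(propensities(net, c(-1, 0, 0), 0), "non-negative")
  expect_error(propensities(net, c(1, 1, 1), -2), "non-negative")
})

test_that("apply_reaction shifts the state by the channel stoichiometry", {
  net <- build_network()
  expect_equal(unname(apply_reaction(net, c(2, 3, 5), "binding")),
               c(1, 2, 6))
  expect_equal(unname(apply_reaction(net, c(2, 3, 5), "cleavage")),
               c(3, 3, 4))
  expect_equal(unname(apply_reaction(net, c(2, 3, 5), "production")),
               c(3, 4, 5)) # the pair is co-produced
  expect_error(apply_reaction(net, c(0, 0, 5), "binding"), "negative")
  expect_error(apply_reaction(net, c(1, 1, 1), "transmogrify"), "unknown")
})

test_that("mean-field derivatives mirror the channels one-to-one", {
  net <- build_network()
  expect_equal(unname(mean_field_rhs(net, c(0, 0, 0), 0)), c(0.1, 0.1, 0))
  # sum rule: d(sigv)/dt - d(rsiv)/dt == L*k_C*C + k_deg*(R - sigma)
  p <- circuit_params()
  set.seed(42)
  for (i in 1:20) {
    st <- runif(3, 0, 300)
    L <- runif(1, 0, 4)
    d <- mean_field_rhs(net, st, L)
    expect_equal(unname(d[1] - d[2]),
                 L * p$k_C * st[3] + p$k_deg * (st[2] - st[1]))
  }
})

test_that("mean-field rhs agrees with finite differences of the ODE path", {
  net <- build_network()
  times <- seq(0, 400, by = 0.5)
  path <- mean_field_path(net, constant_protocol(1, 400), times,
                          init = c(0, 0, 0))
  i <- c(100, 300, 600)
  for (k in i) {
    fd <- (unlist(path[k + 1, c("sigv", "rsiv", "complex")]) -
             unlist(path[k - 1, c("sigv", "rsiv", "complex")])) / 1
    an <- mean_field_rhs(net, unlist(path[k, c("sigv", "rsiv", "complex")]),
                         L = 1)
    expect_equal(unname(fd), unname(an), tolerance = 1e-3)
  }
})

test_that("steady state solves the fixed point and responds to stress", {
  # leak-only, no binding: closed form sigma* = R* = v0/k_deg, C* = 0
  net0 <- build_network(circuit_params(v = 0, k_B = 0))
  ss0 <- steady_state(net0, 0)
  expect_equal(ss0$sigv, 10, tolerance = 1e-6)
  expect_equal(ss0$rsiv, 10, tolerance = 1e-6)
  expect_equal(ss0$complex, 0, tolerance = 1e-6)

  net <- build_network()
  ss <- steady_state(net, 0)
  # all derivatives vanish at the returned state
  expect_lt(max(abs(mean_field_rhs(net, c(ss$sigv, ss$rsiv, ss$complex), 0))),
            1e-8)
  # agreement with long-time integration from the zero state
  long <- mean_field_path(net, constant_protocol(0, 1e5), c(0, 5e4, 1e5))
  expect_equal(ss$sigv, long$sigv[3], tolerance = 1e-6)
  # stress raises the free sigma-V fixed point
  ss1 <- steady_state(net, 1)
  expect_gt(ss1$sigv, ss$sigv)
})

test_that("system-size scaling preserves the intensive mean-field dynamics", {
  p <- circuit_params()
  omega <- 50
  net1 <- build_network(p)
  netW <- build_network(scale_system_size(p, omega))
  set.seed(7)
  for (i in 1:10) {
    st <- runif(3, 0, 200)
    L <- runif(1, 0, 2)
    expect_equal(unname(mean_field_rhs(netW, st * omega, L) / omega),
                 unname(mean_field_rhs(net1, st, L)), tolerance = 1e-12)
  }
})
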