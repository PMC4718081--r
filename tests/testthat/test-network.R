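test_that("calibration solves production so the baseline is a fixed point", {
  # decoupled case: gains 0 reduce to three turnover equations
  chains0 <- lapply(default_chains(), function(ch) {
    ch$gain <- 0
    ch
  })
  net0 <- build_network(c(abeta = 2, tau = 3, ptau = 4),
                        clearance = c(abeta = 0.5, tau = 1, ptau = 2),
                        chains = chains0)
  expect_equal(net0$production,
               c(abeta = 1, tau = 3, ptau = 8))
  # default gains: steady state returns the baseline
  net <- build_network(c(abeta = 1, tau = 1, ptau = 1))
  expect_lt(max(abs(steady_state(net) - net$baseline)), 1e-8)
})

test_that("calibration residual < 1e-8 on random positive baselines", {
  set.seed(17)
  for (i in 1:20) {
    b <- setNames(exp(runif(3, -1, 2)), marker_names())
    net <- build_network(b)
    state <- setNames(
      c(b, unlist(lapply(net$chains,
                         function(ch) rep(b[[ch$source]], ch$n_compartments)))),
      net$state_names)
    # residual of the ODE right-hand side at the claimed fixed point
    expect_lt(max(abs(network_rhs(net, state)) / max(b)), 1e-8)
    expect_lt(max(abs(steady_state(net) - b) / b), 1e-8)
  }
})

test_that("the baseline state is numerically stationary under integration", {
  net <- build_network()
  traj <- simulate_network(net, duration = 10, step = 0.1)
  mk <- as.matrix(traj[, marker_names()])
  expect_lt(max(abs(sweep(mk, 2, net$baseline, "/") - 1)), 1e-6)
})

test_that("an isolated chain delays input like an Erlang density", {
  ch <- transit_chain("abeta", "ptau", n_compartments = 3, tau = 0.5)
  ir <- chain_impulse_response(ch)
  # closed-form Erlang(n, 1/tau) oracle for the outflux shape
  expected <- dgamma(ir$time, shape = 3, scale = 0.5)
  expect_lt(max(abs(ir$flux - expected)), 1e-6)
  expect_lt(abs(mean_transit_time(ch) / (3 * 0.5) - 1), 0.01)
  # chain-delay law: doubling tau doubles the mean transit time
  ch2 <- transit_chain("abeta", "ptau", n_compartments = 3, tau = 1.0)
  expect_lt(abs(mean_transit_time(ch2) / (2 * mean_transit_time(ch)) - 1),
            0.01)
  # and a different length
  ch5 <- transit_chain("tau", "ptau", n_compartments = 5, tau = 0.3)
  expect_lt(abs(mean_transit_time(ch5) / (5 * 0.3) - 1), 0.01)
})

test_that("the default network is linearly stable and relaxes impulses", {
  net <- build_network()
  # independent linear-stability oracle: finite-difference Jacobian at the
  # fixed point must have eigenvalues with negative real part
  state0 <- setNames(
    c(net$baseline,
      unlist(lapply(net$chains,
                    function(ch) rep(net$baseline[[ch$source]],
                                     ch$n_compartments)))),
    net$state_names)
  n <- length(state0)
  J <- matrix(0, n, n)
  h <- 1e-7
  for (j in seq_len(n)) {
    up <- state0; up[j] <- up[j] + h
    dn <- state0; dn[j] <- dn[j] - h
    J[, j] <- (network_rhs(net, up) - network_rhs(net, dn)) / (2 * h)
  }
  expect_true(all(Re(eigen(J, only.values = TRUE)$values) < 0))
  # a 10% amyloid impulse decays back to baseline
  out <- propagate_perturbation(net, net$baseline * c(1.1, 1, 1),
                                horizon = 60)
  expect_lt(max(abs(out / net$baseline - 1)), 0.01)
})

test_that("propagate_perturbation honours identity and coupling direction", {
  net <- build_network()
  expect_equal(propagate_perturbation(net, net$baseline, horizon = 5),
               net$baseline, tolerance = 1e-6)
  # zero horizon returns the perturbation unchanged
  v <- c(abeta = 1.3, tau = 0.9, ptau = 1.1)
  expect_identical(propagate_perturbation(net, v, horizon = 0), v)
  # raised amyloid stimulates P-tau above baseline at a moderate horizon
  out <- propagate_perturbation(net, net$baseline * c(1.5, 1, 1),
                                horizon = 2)
  expect_gt(out[["ptau"]], net$baseline[["ptau"]])
  # with all gains zero a long horizon relaxes to baseline (pure turnover)
  chains0 <- lapply(default_chains(), function(ch) {
    ch$gain <- 0
    ch
  })
  net0 <- build_network(chains = chains0)
  out0 <- propagate_perturbation(net0, c(abeta = 2, tau = 0.5, ptau = 1.7),
                                 horizon = 40)
  expect_lt(max(abs(out0 - net0$baseline)), 1e-4)
})

test_that("trajectories stay non-negative from non-negative starts", {
  net <- build_network()
  set.seed(8)
  for (i in 1:5) {
    init <- setNames(runif(length(net$state_names), 0, 3), net$state_names)
    traj <- simulate_network(net, init, duration = 20, step = 0.2)
    expect_true(all(as.matrix(traj[, -1]) >= 0))
  }
  expect_error(simulate_network(net, duration = -1))
})
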