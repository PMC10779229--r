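# Voltage-dependent rates, generator construction, equilibrium and the
# spectral master-equation solver.

test_that("transition rates follow the exponential rate laws", {
  p <- transition_params(alpha0 = 0.1, beta0 = 0.2, x = 0.5, z_delta = 1)

  r0 <- transition_rates(p, V = 0, temperature = 295.15)
  expect_equal(r0$alpha, 0.1)
  expect_equal(r0$beta, 0.2)

  # V chosen so x*z_delta*V = kT/e0 exactly
  vt <- thermal_voltage_mV(295.15)
  r1 <- transition_rates(p, V = 2 * vt, temperature = 295.15)
  expect_equal(r1$alpha, 0.1 * exp(1), tolerance = 1e-12)
  expect_equal(r1$beta, 0.2 * exp(-1), tolerance = 1e-12)

  # detailed balance: alpha/beta moves the full step charge
  for (V in c(-120, -30, 0, 55, 140)) {
    r <- transition_rates(p, V)
    expect_equal(r$alpha / r$beta, (0.1 / 0.2) * exp(1 * V / vt),
                 tolerance = 1e-12)
  }

  expect_error(transition_rates(p, NaN), "finite")
  expect_error(transition_rates(p, 10, temperature = -1), "positive")
})

test_that("generator has chain structure and conserves probability", {
  G2 <- build_generator(two_state_scheme(1, 1), V = 0)
  expect_equal(unname(G2), matrix(c(-1, 1, 1, -1), 2, 2, byrow = TRUE))

  for (seed in 1:10) {
    sch <- random_scheme(seed)
    V <- withr::with_seed(seed + 100, runif(1, -120, 180))
    G <- build_generator(sch, V)
    expect_equal(max(abs(rowSums(G))), 0, tolerance = 1e-12)
    offdiag <- G[row(G) != col(G)]
    expect_true(all(offdiag >= 0))
    # linear 5-state chain: exactly 8 nearest-neighbour couplings
    expect_identical(sum(offdiag > 0), 8L)
    expect_true(all(G[abs(row(G) - col(G)) > 1] == 0))
  }
})

test_that("equilibrium occupancy matches detailed balance", {
  expect_equal(unname(equilibrium_occupancy(two_state_scheme(1, 1), 0)),
               c(0.5, 0.5), tolerance = 1e-12)

  sch2 <- two_state_scheme(0.3, 0.7)
  p <- equilibrium_occupancy(sch2, 25)
  r <- transition_rates(sch2$transitions[[1]], 25)
  expect_equal(p[[2]] / p[[1]], r$alpha / r$beta, tolerance = 1e-10)

  # 5-state chain: product of Boltzmann factors along the chain
  for (seed in 1:10) {
    sch <- random_scheme(seed)
    V <- withr::with_seed(seed + 200, runif(1, -120, 180))
    p <- equilibrium_occupancy(sch, V)
    ratios <- vapply(sch$transitions, function(tp) {
      r <- transition_rates(tp, V, sch$temperature)
      r$alpha / r$beta
    }, numeric(1))
    p_oracle <- c(1, cumprod(ratios))
    p_oracle <- p_oracle / sum(p_oracle)
    expect_equal(unname(p), p_oracle, tolerance = 1e-10)
    # stationarity under the generator
    expect_lt(max(abs(p %*% build_generator(sch, V))), 1e-10)
  }
})

test_that("spectral solution agrees with matrix-exponential and RK4 oracles", {
  times <- c(0, 0.05, 0.1, 0.2, 0.5)
  p0 <- c(1, 0, 0, 0, 0)
  for (seed in 1:100) {
    sch <- random_scheme(seed)
    V <- withr::with_seed(seed + 300, runif(1, -120, 180))
    traj <- solve_occupancies(sch, V, p0, times)
    expect_equal(unname(rowSums(traj$occupancy)), rep(1, length(times)),
                 tolerance = 1e-9)
    G <- build_generator(sch, V)
    P_expm <- t(vapply(times, function(tt) {
      as.vector(p0 %*% as.matrix(Matrix::expm(G * tt)))
    }, numeric(5)))
    expect_lt(max(abs(traj$occupancy - P_expm)), 1e-7)
  }
  # fourth-order Runge-Kutta oracle at dt = 1e-4 ms on a subset
  skip_if_not_installed("deSolve")
  for (seed in 1:15) {
    sch <- random_scheme(seed)
    V <- withr::with_seed(seed + 300, runif(1, -120, 180))
    G <- build_generator(sch, V)
    sol <- deSolve::ode(y = p0, times = seq(0, 0.5, by = 1e-4),
                        func = function(t, y, parms) list(as.vector(y %*% G)),
                        parms = NULL, method = "rk4")
    traj <- solve_occupancies(sch, V, p0, times)
    at <- vapply(times, function(tt) which.min(abs(sol[, 1] - tt)), integer(1))
    expect_lt(max(abs(traj$occupancy - sol[at, -1])), 1e-7)
  }
})

test_that("relaxation follows the two-state closed form and reaches equilibrium", {
  sch <- two_state_scheme(0.8, 0.4)
  V <- 30
  r <- transition_rates(sch$transitions[[1]], V)
  p_eq <- equilibrium_occupancy(sch, V)
  times <- seq(0, 10, by = 0.05)
  traj <- solve_occupancies(sch, V, c(1, 0), times)
  expected_p1 <- p_eq[[1]] + (1 - p_eq[[1]]) * exp(-(r$alpha + r$beta) * times)
  expect_equal(unname(traj$occupancy[, 1]), unname(expected_p1),
               tolerance = 1e-9)
  expect_equal(unname(traj$occupancy[nrow(traj$occupancy), ]),
               unname(p_eq), tolerance = 1e-6)

  # starting at equilibrium the occupancy is constant
  traj_eq <- solve_occupancies(sch, V, p_eq, times)
  expect_equal(max(abs(sweep(traj_eq$occupancy, 2, p_eq))), 0,
               tolerance = 1e-9)
})

test_that("gating current integrates to N e0 times the displaced charge", {
  sch <- two_state_scheme(2, 1, n_channels = 1e9)
  V <- 80
  times <- seq(0, 30, by = 0.01)
  traj <- solve_occupancies(sch, V, c(1, 0), times)
  z <- state_charges(sch)

  # stationary occupancy gives zero current (bound scales with N e0 ~ 1e5)
  p_eq <- equilibrium_occupancy(sch, V)
  traj_eq <- solve_occupancies(sch, V, p_eq, times)
  expect_lt(max(abs(gating_current(traj_eq, z, 1e9, scheme = sch))), 1e-7)

  I <- gating_current(traj, z, 1e9, scheme = sch)
  q_total <- pracma::trapz(times, I)
  dp <- traj$occupancy[length(times), 2] - traj$occupancy[1, 2]
  # trapezoidal quadrature of the initial transient limits the agreement
  expect_equal(q_total, 1e9 * e0_fC * dp, tolerance = 2e-3)

  # finite-difference fallback agrees with the exact readout
  I_fd <- gating_current(traj, z, 1e9)
  expect_equal(pracma::trapz(times, I_fd), q_total, tolerance = 2e-3)

  expect_error(gating_current(traj, c(0, 1, 2), 1e9), "match")
})

test_that("protocol simulation conserves probability and charge", {
  sch <- example_scheme("conservative")
  # hold only: no charge moves
  hold <- simulate_protocol(sch, voltage_protocol(c(20), c(-90), 0.05))
  expect_lt(max(abs(hold$current)), 1e-9 * sch$n_channels * e0_fC)

  sw <- simulate_protocol(sch,
    voltage_protocol(c(5, 20, 120), c(-90, 150, -90), 0.02))
  expect_equal(unname(rowSums(sw$occupancy)),
               rep(1, length(sw$times)), tolerance = 1e-9)

  # full relaxation back to the holding potential: ON and OFF charge match
  q_on <- integrate_charge(sw, c(5, 24.98), baseline = 0)
  q_off <- integrate_charge(sw, c(25, 145), baseline = 0)
  expect_equal(q_off / q_on, 1, tolerance = 0.01)

  # reversing a full relaxation negates the integrated charge
  z <- state_charges(sch)
  up <- solve_occupancies(sch, 150, equilibrium_occupancy(sch, -90),
                          seq(0, 100, 0.01))
  dn <- solve_occupancies(sch, -90, equilibrium_occupancy(sch, 150),
                          seq(0, 100, 0.01))
  q_up <- pracma::trapz(up$times, gating_current(up, z, 1e7, scheme = sch))
  q_dn <- pracma::trapz(dn$times, gating_current(dn, z, 1e7, scheme = sch))
  # quadrature of the fast initial transients limits the cancellation
  expect_equal(q_up, -q_dn, tolerance = 2e-3)

  # trapping scheme: OFF charge over the first 20 ms falls short of ON
  swt <- simulate_protocol(example_scheme("trapping"),
    voltage_protocol(c(5, 30, 60), c(-90, 200, 0), 0.05))
  q_on_t <- integrate_charge(swt, c(5, 34.95), baseline = 0)
  q_off_t <- integrate_charge(swt, c(35, 55), baseline = 0)
  expect_lt(q_off_t / q_on_t, 0.9)

  expect_error(voltage_protocol(numeric(0), numeric(0)), "length")
})

test_that("scheme and protocol validation rejects malformed input", {
  expect_error(transition_params(-1, 1), "alpha0")
  expect_error(transition_params(1, 1, x = 2))
  expect_error(kinetic_scheme(list(1, 2)), "transition_params")
  expect_error(voltage_protocol(c(5, -1), c(0, 0)))
  expect_error(solve_occupancies(two_state_scheme(), 0, c(0.7, 0.7), 0:3),
               "sum to 1")
})
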