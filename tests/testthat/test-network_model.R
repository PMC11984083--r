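test_that("network_params validates its invariants", {
  expect_error(network_params(1, -1, 1, 0, 10), "gamma")
  expect_error(network_params(1, 1, -1, 0, 10), "K")
  expect_error(network_params(1, 1, 1, -1, 10), "D")
  expect_error(network_params(1, 1, 1, 0, 0), "N")
  expect_error(network_params(1, 1, 1, 0, 10, Z = function(x) x), "periodic")
  p <- network_params(2 * pi * 30, 0, 0, 0, 3)
  expect_s3_class(p, "network_params")
  expect_true(p$z_is_neg_sin)
})

test_that("natural frequencies follow the Cauchy law", {
  p0 <- network_params(2 * pi * 30, 0, 0, 0, 100)
  expect_equal(sample_natural_frequencies(p0, seed = 1),
               rep(2 * pi * 30, 100))
  p <- network_params(2 * pi * 30, 2 * pi, 0, 0, 1e5)
  w <- sample_natural_frequencies(p, seed = 7)
  # Cauchy median = location, half the IQR = scale
  expect_lt(abs(median(w) - 2 * pi * 30), 2 * pi * 0.05)
  expect_lt(abs(diff(quantile(w, c(0.25, 0.75))) / 2 - 2 * pi) / (2 * pi),
            0.05)
  expect_identical(w, sample_natural_frequencies(p, seed = 7))
  wt <- sample_natural_frequencies(p, seed = 7, truncate_at = 2 * pi * 5)
  expect_lte(max(abs(wt - 2 * pi * 30)), 2 * pi * 5 + 1e-9)
})

test_that("order parameter matches hand evaluations", {
  op <- order_parameter(rep(0.7, 3))
  expect_equal(op$rho, 1)
  expect_equal(op$psi, 0.7)
  expect_lt(order_parameter(c(0, pi))$rho, 1e-15)
  op2 <- order_parameter(c(0, pi / 2))
  expect_equal(op2$rho, sqrt(2) / 2)
  expect_equal(op2$psi, pi / 4)
  expect_error(order_parameter(numeric(0)), "nonempty")
  # psi convention at rho ~ 0
  expect_identical(order_parameter(c(0, pi))$psi, 0)
})

test_that("a single Euler step matches hand evaluations", {
  p1 <- network_params(1, 0, 0, 0, 1)
  expect_equal(step_phases(0.3, 2, p1, dt = 0.05), 0.3 + 2 * 0.05)
  p2 <- network_params(0, 0, 1, 0, 2)
  out <- step_phases(c(0, pi / 2), c(0, 0), p2, dt = 0.1)
  expect_equal(out, c(0.05, pi / 2 - 0.05))
  expect_error(step_phases(0, 1, p1, dt = 0), "dt")
})

test_that("noise increments have Brownian variance 2 D dt", {
  p <- network_params(0, 0, 0, D = 0.8, N = 1e4)
  dt <- 2e-3
  set.seed(42)
  out <- step_phases(rep(0, 1e4), rep(0, 1e4), p, dt = dt)
  expect_lt(abs(var(out) / (2 * 0.8 * dt) - 1), 0.05)
})

test_that("compiled simulator agrees with the pairwise-sum R oracle", {
  p <- network_params(2 * pi * 25, 2 * pi, 3 * 2 * pi, 0, 8)
  set.seed(3)
  omega <- sample_natural_frequencies(p)
  theta <- runif(8, -pi, pi)
  dt <- 5e-4
  tr <- simulate_network(p, NULL, duration = 50 * dt, dt = dt, seed = 1,
                         theta0 = theta, omega = omega, store_theta = TRUE)
  th_r <- theta
  for (s in 1:50) th_r <- step_phases(th_r, omega, p, dt)
  expect_equal(unname(tr$theta[51, ]), wrap_phase(th_r), tolerance = 1e-10)
})

test_that("free rotation conserves phase differences exactly", {
  p <- network_params(2 * pi * 20, 2 * pi, 0, 0, 5)
  set.seed(9)
  omega <- sample_natural_frequencies(p)
  theta0 <- runif(5, -pi, pi)
  tr <- simulate_network(p, NULL, 0.25, dt = 5e-4, seed = 2,
                         theta0 = theta0, omega = omega, store_theta = TRUE)
  t_end <- tr$times[length(tr$times)]
  expect_equal(unname(tr$theta[nrow(tr$theta), ]),
               wrap_phase(theta0 + omega * t_end), tolerance = 1e-9)
})

test_that("trajectories are deterministic given the seed", {
  p <- quick_params(N = 40)
  proto <- stim_protocol(0, 0.05)
  a <- simulate_network(p, proto, 3, seed = 123)
  b <- simulate_network(p, proto, 3, seed = 123)
  expect_identical(a$rho, b$rho)
  expect_identical(a$pulse_times, b$pulse_times)
  c <- simulate_network(p, proto, 3, seed = 124)
  expect_false(identical(a$rho, c$rho))
})

test_that("rho stays in [0, 1] across regimes", {
  for (sd in 1:5) {
    p <- quick_params(N = 30, K = runif(1, 0, 30), D = runif(1, 0, 8))
    tr <- simulate_network(p, NULL, 1, seed = sd)
    expect_true(all(tr$rho >= 0 & tr$rho <= 1))
  }
})

test_that("controller fires once per cycle under uniform rotation", {
  p <- network_params(2 * pi * 30, 0, 0, 0, 10)
  proto <- stim_protocol(0, 1e-9, 0.8, data.frame(off_s = 0.5, on_s = 2))
  tr <- simulate_network(p, proto, 2.5, seed = 1,
                         omega = rep(2 * pi * 30, 10),
                         theta0 = rep(0.1, 10))
  expect_equal(length(tr$pulse_times), 60)
  expect_true(all(abs(diff(tr$pulse_times) - 1 / 30) < 1e-3))
  expect_true(all(tr$pulse_times >= 0.5 & tr$pulse_times <= 2.5))
})

test_that("refractory rule suppresses close crossings", {
  # constructed mean-phase series with two upward crossings 10 ms apart
  fs <- 2000
  times <- (0:400) / fs
  psi <- rep(-0.5, length(times))
  psi[times >= 0.050] <- 0.5   # first crossing at 50 ms
  psi[times >= 0.055 & times < 0.060] <- -0.5
  psi[times >= 0.060] <- 0.5   # second crossing at 60 ms
  pc <- phase_crossings(times, psi, 0, refractory_s = 0.8 / 30)
  expect_equal(length(pc), 1)
  expect_equal(pc, 0.050)
  # without refractory both crossings fire
  expect_equal(length(phase_crossings(times, psi, 0, 0)), 2)
  # never crossing: no pulses
  expect_length(phase_crossings(times, rep(0.3, length(times)), 2, 0), 0)
})

test_that("network signal is rho cos psi with unit envelope when locked", {
  p <- network_params(2 * pi * 30, 0, 0, 0, 20)
  tr <- simulate_network(p, NULL, 2, seed = 1,
                         omega = rep(2 * pi * 30, 20),
                         theta0 = rep(0, 20))
  expect_equal(tr$signal, cos(2 * pi * 30 * tr$times), tolerance = 1e-8)
  expect_equal(network_signal(tr), tr$signal)
  set.seed(1)
  noisy <- network_signal(tr, measurement_noise_sd = 0.1)
  expect_gt(sd(noisy - tr$signal), 0.09)
})

test_that("Hilbert envelope of the signal tracks synchrony", {
  p <- quick_params(N = 300)
  tr <- simulate_network(p, NULL, 20, seed = 8)
  ab <- analytic(bandpass(recording(tr$signal, 2000)))
  interior <- tr$times > 1 & tr$times < 19
  expect_gt(cor(ab$envelope[interior], tr$rho[interior]), 0.9)
})

test_that("stimulation phase controls the direction of the rho change", {
  p <- quick_params(N = 100)
  deltas <- sapply(1:20, function(sd) {
    base <- simulate_network(p, NULL, 6, seed = sd)
    amp <- simulate_network(p, stim_protocol(0, 0.05, 0.8,
                  data.frame(off_s = 1, on_s = 5)), 6, seed = sd)
    sup <- simulate_network(p, stim_protocol(pi, 0.05, 0.8,
                  data.frame(off_s = 1, on_s = 5)), 6, seed = sd)
    sel <- base$times > 1.5
    c(mean(amp$rho[sel]) - mean(base$rho[sel]),
      mean(sup$rho[sel]) - mean(base$rho[sel]))
  })
  expect_gt(mean(deltas[1, ]), 0)   # stimulating at psi ~ 0 amplifies
  expect_lt(mean(deltas[2, ]), 0)   # stimulating at psi ~ pi suppresses
})

test_that("wrapped-Cauchy initial phases realize the requested synchrony", {
  set.seed(5)
  th <- init_phases_wrapped_cauchy(20000, 0.6, 1.2)
  op <- order_parameter(th)
  expect_lt(abs(op$rho - 0.6), 0.02)
  expect_lt(abs(op$psi - 1.2), 0.05)
  expect_error(init_phases_wrapped_cauchy(10, 1.2), "rho")
})

test_that("halving the time step barely changes the mean synchrony", {
  p <- network_params(2 * pi * 30, 2 * pi, 8 * pi, 0, 500)
  set.seed(17)
  omega <- sample_natural_frequencies(p)
  theta0 <- init_phases_wrapped_cauchy(500, 0.5)
  a <- simulate_network(p, NULL, 10, dt = 5e-4, seed = 1,
                        theta0 = theta0, omega = omega)
  b <- simulate_network(p, NULL, 10, dt = 2.5e-4, seed = 1,
                        theta0 = theta0, omega = omega)
  ra <- mean(a$rho[a$times > 1])
  rb <- mean(b$rho[b$times > 1])
  expect_lt(abs(ra - rb) / rb, 0.01)
})
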