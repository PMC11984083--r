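test_that("block ARC is the on-minus-off mean envelope", {
  fs <- 2000
  env <- c(rep(1, 5 * fs), rep(1.3, 5 * fs))
  ab <- analytic_stub(envelope = env, fs = fs)
  expect_equal(block_arc(ab, c(0, 4.999), c(5, 9.999)), 0.3, tolerance = 1e-3)
  expect_equal(block_arc(ab, c(0, 2), c(2.5, 4.5)), 0)
})

test_that("block PRC recovers injected per-pulse phase shifts", {
  fs <- 2000
  t <- (0:(25 * fs - 1)) / fs
  omega <- 2 * pi * 30
  # pure ramp, no stimulation effect: exactly zero
  ab <- analytic_stub(phase_unwrapped = omega * t, fs = fs)
  expect_equal(block_prc(ab, c(0, 5), c(5, 25), n_pulses = 40), 0,
               tolerance = 1e-10)
  # ramp plus n_pulses jumps of +delta during the on-epoch -> -delta
  delta <- 0.05
  pt <- seq(5.2, 24.8, length.out = 40)
  ph <- omega * t
  for (tp in pt) ph[t >= tp] <- ph[t >= tp] + delta
  ab2 <- analytic_stub(phase_unwrapped = ph, fs = fs)
  expect_equal(block_prc(ab2, c(0, 5), c(5, 25), n_pulses = 40), -delta,
               tolerance = 1e-6)
  expect_error(block_prc(ab2, c(0, 5), c(5, 25), n_pulses = 0), "n_pulses")
})

test_that("block PRC is unbiased under symmetric phase noise", {
  fs <- 500
  t <- (0:(25 * fs - 1)) / fs
  set.seed(14)
  vals <- replicate(100, {
    ph <- 2 * pi * 30 * t + rnorm(length(t), sd = 0.05)
    block_prc(analytic_stub(phase_unwrapped = ph, fs = fs),
              c(0, 5), c(5, 25), n_pulses = 30)
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("pulse-based ARC measures the around-pulse envelope step", {
  fs <- 2000
  env <- rep(2, 2 * fs)
  ab <- analytic_stub(envelope = env, fs = fs)
  pa <- pulse_arc(ab, pulse_times = c(0.5, 1.0, 1.5))
  expect_equal(pa$delta_amp, rep(0, 3))
  expect_equal(pa$pre_amp, rep(2, 3))
  env2 <- c(rep(1, fs), rep(1.6, fs))  # step at t = 1.0 s
  pa2 <- pulse_arc(analytic_stub(envelope = env2, fs = fs),
                   pulse_times = 1.0)
  expect_equal(pa2$delta_amp, 0.6, tolerance = 1e-6)
  # overlapping windows flagged, both kept
  pa3 <- pulse_arc(ab, pulse_times = c(1.0, 1.004))
  expect_equal(nrow(pa3), 2)
  expect_true(pa3$overlap[2])
})

test_that("circular central difference matches its closed form", {
  expect_equal(prc_derivative(rep(2, 8)), rep(0, 8))
  phi <- seq(0, 2 * pi, length.out = 9)[-9]
  d <- prc_derivative(sin(phi))
  expect_equal(d, cos(phi) * sin(pi / 4) / (pi / 4), tolerance = 1e-12)
  u <- rnorm(8); v <- rnorm(8)
  expect_equal(prc_derivative(3 * u - 2 * v),
               3 * prc_derivative(u) - 2 * prc_derivative(v))
  expect_error(prc_derivative(c(1, 2)), "3 points")
})

test_that("alignment rotates the ARC minimum into the reference slot", {
  phi <- wrap_phase(seq(0, 2 * pi, length.out = 9)[-9])
  arc <- -cos(phi)  # minimum at slot 1 already
  rcs <- response_curve_set(phi, arc, sin(phi))
  al <- align_most_suppressive(rcs)
  expect_equal(al$alignment_offset, 0)
  expect_equal(al$arc, arc)
  # rotate by 3 slots and realign: inverse rotation recovered
  rot <- response_curve_set(phi, arc[c(6:8, 1:5)], sin(phi)[c(6:8, 1:5)])
  al2 <- align_most_suppressive(rot)
  expect_equal(which.min(al2$arc), 1L)
  expect_equal(al2$arc, arc)
  # two curve sets with different offsets coincide after alignment
  rot2 <- response_curve_set(phi, arc[c(4:8, 1:3)], sin(phi)[c(4:8, 1:3)])
  expect_equal(align_most_suppressive(rot2)$arc, al2$arc)
})

test_that("one-way ANOVA p-values are calibrated and powered", {
  set.seed(21)
  # null: p uniform on (0, 1)
  pn <- replicate(1000, {
    v <- rnorm(8 * 12)
    phase_dependence_anova(v, rep(1:8, each = 12))
  })
  expect_gt(ks.test(pn, "punif")$p.value, 0.01)
  # strong phase effect: tiny p
  v <- rep(sin(2 * pi * (1:8) / 8), each = 12) + rnorm(96, sd = 0.3)
  expect_lt(phase_dependence_anova(v, rep(1:8, each = 12)), 1e-3)
  expect_error(phase_dependence_anova(rep(1, 16), rep(1:8, 2)), "undefined")
  expect_error(phase_dependence_anova(rnorm(8), 1:8), "groups")
})

test_that("correlation measures behave at the extremes and under the null", {
  d <- rnorm(16)
  ct <- arc_prc_correlation(-3 * d, d)
  expect_equal(ct$R, -1)
  set.seed(31)
  frac <- mean(replicate(200, arc_prc_correlation(rnorm(8), rnorm(8))$p) < 0.05)
  expect_lt(frac, 0.15)
  expect_error(arc_prc_correlation(rep(1, 8), rnorm(8)), "variance")
  sl <- spearman_link(c(0.9, 0.8, 0.5, 0.2), c(1e-4, 1e-3, 0.2, 0.6))
  expect_equal(sl$rs, -1)
})

test_that("amplitude-dependence regressions recover constructed effects", {
  set.seed(7)
  n <- 40
  pre <- rnorm(n, 1, 0.15)
  # regression to the mean in the reference + a pre-independent offset
  ref <- data.frame(pre_amp = pre, arc_value = -0.5 * (pre - 1) +
                      rnorm(n, sd = 0.01), condition = "reference")
  amp <- data.frame(pre_amp = pre, arc_value = -0.5 * (pre - 1) + 0.2 +
                      rnorm(n, sd = 0.01), condition = "amplifying")
  out <- block_amplitude_dependence(rbind(ref, amp))
  expect_lt(out$fits$reference$slope, 0)
  expect_equal(out$reference_subtracted$amplifying$mean_effect, 0.2,
               tolerance = 0.02)
  expect_lt(abs(out$reference_subtracted$amplifying$slope), 0.1)
  expect_warning(block_amplitude_dependence(
    rbind(ref, data.frame(pre_amp = 1, arc_value = 0,
                          condition = "suppressive"))), "5 blocks")
})

test_that("estimator pipeline recovers constructed ground truth end to end", {
  cs <- make_constructed_signal(delta_phase = 0.04, amp_step = 0.01,
                                n_pulses_per_block = 30, n_blocks = 3,
                                seed = 2)
  rec <- cs$recording
  gt <- cs$ground_truth
  ab <- analytic(bandpass(rec))
  ep <- rec$epochs
  arcs <- prcs <- numeric(0)
  for (b in which(ep$label == "on")) {
    off_iv <- c(ep$start[b - 1], ep$end[b - 1])
    on_iv <- c(ep$start[b], ep$end[b])
    arcs <- c(arcs, block_arc(ab, off_iv, on_iv))
    prcs <- c(prcs, block_prc(ab, off_iv, on_iv, 30))
  }
  expect_equal(mean(arcs), gt$injected_arc, tolerance = 0.05)
  expect_equal(mean(prcs), gt$injected_prc, tolerance = 0.05)
})

test_that("amplifying-phase pulses raise the pulse-based amplitude response", {
  # quantified on the model synchrony series: zero-phase filtering spreads
  # an instantaneous kick symmetrically across the +/-10 ms windows, so the
  # Hilbert-envelope route cannot resolve single-pulse effects
  p <- default_network_params()
  proto <- stim_protocol(0, 0.12, 0.8, default_block_layout(2, 5, 20))
  tr <- simulate_network(p, proto, 51, seed = 33)
  base <- simulate_network(p, NULL, 51, seed = 33)
  pa <- pulse_arc(analytic_stub(envelope = tr$rho, fs = 2000),
                  tr$pulse_times)
  ref <- pulse_arc(analytic_stub(envelope = base$rho, fs = 2000),
                   tr$pulse_times)  # matched pulse-free reference times
  expect_gt(nrow(pa), 200)
  tt <- t.test(pa$delta_amp, ref$delta_amp, alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
})
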