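#' Parameters of the finite stochastic Kuramoto network
#'
#' Bundles the parameters of a population of `N` all-to-all coupled phase
#' oscillators with natural frequencies drawn from a Cauchy (Lorentzian)
#' distribution and independent white phase noise.  Each oscillator responds
#' to a stimulation impulse through its phase-response function `Z`; the
#' default `Z(theta) = -sin(theta)` captures the biphasic (type II) response
#' of regularly spiking neurons, with a slow-down region just after the
#' spike and a speed-up region just before the next one.
#'
#' @param omega0 Mean natural frequency (rad/s).
#' @param gamma Half-width of the Cauchy frequency distribution (rad/s),
#'   `>= 0`.
#' @param K Global coupling constant (rad/s), `>= 0`.
#' @param D Noise intensity (rad^2/s), `>= 0`; the per-oscillator white
#'   noise satisfies `<xi_i(t) xi_j(t')> = 2 D delta(t - t') delta_ij`.
#' @param N Number of oscillators (positive integer).
#' @param Z Phase-response function, a 2*pi-periodic function of phase;
#'   default `function(theta) -sin(theta)`.  Periodicity is checked on a
#'   grid at construction.
#' @return An object of class `network_params`.
#' @examples
#' p <- network_params(omega0 = 2 * pi * 30, gamma = 2 * pi, K = 8 * pi,
#'                     D = 0, N = 200)
#' @export
network_params <- function(omega0, gamma, K, D, N,
                           Z = function(theta) -sin(theta)) {
  stopifnot(is.numeric(omega0), length(omega0) == 1L, is.finite(omega0))
  if (!is.numeric(gamma) || gamma < 0) stop("gamma must be >= 0")
  if (!is.numeric(K) || K < 0) stop("K must be >= 0")
  if (!is.numeric(D) || D < 0) stop("D must be >= 0")
  if (!is.numeric(N) || N < 1 || N != round(N)) stop("N must be a positive integer")
  if (!is.function(Z)) stop("Z must be a function")
  grid <- seq(-pi, pi, length.out = 33)
  if (max(abs(Z(grid) - Z(grid + 2 * pi))) > 1e-8)
    stop("Z must be 2*pi-periodic")
  structure(list(omega0 = omega0, gamma = gamma, K = K, D = D,
                 N = as.integer(N), Z = Z,
                 z_is_neg_sin = isTRUE(max(abs(Z(grid) + sin(grid))) < 1e-12)),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "Kuramoto network: N = %d, omega0 = %.3g rad/s (%.3g Hz), gamma = %.3g rad/s,\n  K = %.3g rad/s, D = %.3g rad^2/s, Z = %s\n",
    x$N, x$omega0, x$omega0 / (2 * pi), x$gamma, x$K, x$D,
    if (x$z_is_neg_sin) "-sin(theta)" else "custom"))
  invisible(x)
}

#' Phase-locked stimulation protocol
#'
#' Describes a closed-loop protocol in which an instantaneous phase kick
#' `delta theta_i = I_pulse * Z(theta_i)` is delivered whenever the network
#' mean phase crosses `target_phase` in the direction of phase increase,
#' provided more than `refractory_fraction` of a mean-frequency cycle has
#' elapsed since the previous pulse, and only during stimulation-on epochs.
#'
#' @param target_phase Target mean phase (rad), wrapped to `[-pi, pi)`.
#' @param pulse_magnitude Kick strength `I_pulse` (rad), `>= 0`.
#' @param refractory_fraction Fraction of a `2*pi/omega0` cycle that must
#'   elapse between pulses; default 0.8.
#' @param block_layout Matrix or data frame with columns `off_s`, `on_s`
#'   giving the ordered (off-duration, on-duration) pairs in seconds.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(target_phase = 0, pulse_magnitude = 0.1,
                          refractory_fraction = 0.8,
                          block_layout = default_block_layout()) {
  if (refractory_fraction < 0 || refractory_fraction >= 1)
    stop("refractory_fraction must be in [0, 1)")
  if (pulse_magnitude < 0) stop("pulse_magnitude must be >= 0")
  bl <- as.data.frame(block_layout)
  if (!all(c("off_s", "on_s") %in% names(bl)))
    stop("block_layout needs columns off_s, on_s")
  if (any(bl$off_s <= 0) || any(bl$on_s <= 0)) stop("durations must be > 0")
  structure(list(target_phase = wrap_phase(target_phase),
                 pulse_magnitude = pulse_magnitude,
                 refractory_fraction = refractory_fraction,
                 block_layout = bl),
            class = "stim_protocol")
}

#' Default block layout: 12 blocks of 20 s stimulation preceded by 5 s off
#' @param n_blocks number of blocks
#' @param off_s off-epoch duration (s)
#' @param on_s on-epoch duration (s)
#' @export
default_block_layout <- function(n_blocks = 12, off_s = 5, on_s = 20) {
  data.frame(off_s = rep(off_s, n_blocks), on_s = rep(on_s, n_blocks))
}

#' Wrap angles to [-pi, pi)
#' @param x angles (rad)
#' @export
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi)
  y - pi
}

#' Epoch table of a protocol
#'
#' Expands the block layout into an epoch table with absolute start/end
#' times, starting at `t0`.
#' @param protocol a [stim_protocol()]
#' @param t0 start time offset (s)
#' @return data.frame with columns `start`, `end`, `label` ("off"/"on").
#' @export
protocol_epochs <- function(protocol, t0 = 0) {
  bl <- protocol$block_layout
  starts <- ends <- numeric(0)
  labels <- character(0)
  t <- t0
  for (b in seq_len(nrow(bl))) {
    starts <- c(starts, t, t + bl$off_s[b])
    ends <- c(ends, t + bl$off_s[b], t + bl$off_s[b] + bl$on_s[b])
    labels <- c(labels, "off", "on")
    t <- t + bl$off_s[b] + bl$on_s[b]
  }
  data.frame(start = starts, end = ends, label = labels)
}

#' Sample natural frequencies
#'
#' Draws `N` frequencies from the Cauchy distribution with location
#' `omega0` and scale `gamma`.  Frequencies are not truncated by default
#' (the heavy tails are part of the model); set `truncate_at` to clip at
#' `omega0 +/- truncate_at` for numerical studies.
#'
#' @param params a [network_params()]
#' @param seed integer seed; if `NULL` the current RNG state is used
#' @param truncate_at optional half-width (rad/s) for clipping, default
#'   `Inf` (off)
#' @return numeric vector of length `N` (rad/s)
#' @export
sample_natural_frequencies <- function(params, seed = NULL, truncate_at = Inf) {
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rcauchy(params$N, location = params$omega0, scale = params$gamma)
  if (is.finite(truncate_at))
    w <- pmin(pmax(w, params$omega0 - truncate_at), params$omega0 + truncate_at)
  w
}

#' Kuramoto order parameter
#'
#' Complex mean of the unit phase vectors, `mean(exp(1i * theta)) = rho *
#' exp(1i * psi)`.  `rho` in `[0, 1]` is the network synchrony
#' (proportional to the measured oscillation amplitude) and `psi` the mean
#' phase.  By convention `psi = 0` when `rho < 1e-12` (mean phase
#' undefined).
#'
#' @param theta numeric vector of phases (rad), nonempty
#' @return list with elements `rho`, `psi`
#' @export
order_parameter <- function(theta) {
  if (length(theta) == 0) stop("theta must be nonempty")
  z <- mean(exp(1i * theta))
  rho <- Mod(z)
  list(rho = rho, psi = if (rho < 1e-12) 0 else Arg(z))
}

#' One Euler--Maruyama step of the full network
#'
#' Reference (pairwise-sum) implementation of a single time step:
#' `theta_i <- theta_i + dt * (omega_i + (K/N) * sum_j sin(theta_j -
#' theta_i)) + sqrt(2 D dt) * eta_i`, with an optional instantaneous kick
#' `I_pulse * Z(theta_i)` applied after the drift/diffusion update.  The
#' fast simulator ([simulate_network()]) uses the algebraically equivalent
#' mean-field form of the coupling; this function is the literal form and
#' doubles as its test oracle.
#'
#' @param theta phase vector (rad)
#' @param omega natural frequencies (rad/s), same length
#' @param params a [network_params()]
#' @param dt time step (s), `> 0`
#' @param kick if `TRUE`, apply the pulse kick with magnitude `I_pulse`
#' @param I_pulse kick magnitude (rad)
#' @return updated phase vector
#' @export
step_phases <- function(theta, omega, params, dt, kick = FALSE, I_pulse = 0) {
  if (dt <= 0) stop("dt must be > 0")
  coupling <- vapply(seq_along(theta),
                     function(i) mean(sin(theta - theta[i])),
                     numeric(1)) * params$K
  theta <- theta + dt * (omega + coupling)
  if (params$D > 0)
    theta <- theta + sqrt(2 * params$D * dt) * stats::rnorm(length(theta))
  if (kick) theta <- theta + I_pulse * params$Z(theta)
  theta
}

#' Detect phase-triggered pulse times on a mean-phase series
#'
#' Stand-alone implementation of the controller's trigger rule, applied to
#' an arbitrary `(times, psi)` series: a pulse fires at the first sample at
#' which the wrapped difference `psi - target` changes sign from negative to
#' non-negative (crossing in the direction of phase increase; the jump at
#' the `+/- pi` wrap point is excluded), provided the time since the last
#' pulse exceeds `refractory_s` and, if `epochs` is given, the sample lies
#' in an "on" epoch.  No interpolation between samples is performed.
#'
#' @param times sample times (s)
#' @param psi mean-phase series (rad), same length
#' @param target target phase (rad)
#' @param refractory_s minimum inter-pulse interval (s)
#' @param epochs optional data.frame(start, end, label) restricting firing
#'   to `label == "on"` rows
#' @param rho optional synchrony series; samples with `rho < rho_gate` are
#'   ignored
#' @param rho_gate synchrony gate, default `1e-6`
#' @return numeric vector of pulse times
#' @export
phase_crossings <- function(times, psi, target, refractory_s,
                            epochs = NULL, rho = NULL, rho_gate = 1e-6) {
  d <- wrap_phase(psi - target)
  n <- length(times)
  on_ok <- rep(TRUE, n)
  if (!is.null(epochs)) {
    on_ok <- rep(FALSE, n)
    on <- epochs[epochs$label == "on", , drop = FALSE]
    for (k in seq_len(nrow(on)))
      on_ok <- on_ok | (times >= on$start[k] & times <= on$end[k])
  }
  if (!is.null(rho)) on_ok <- on_ok & (rho > rho_gate)
  pulses <- numeric(0)
  last <- -Inf
  for (s in 2:n) {
    if (!on_ok[s] || !on_ok[s - 1]) next
    if (d[s - 1] < 0 && d[s] >= 0 && (d[s] - d[s - 1]) < pi &&
        (times[s] - last) > refractory_s) {
      pulses <- c(pulses, times[s])
      last <- times[s]
    }
  }
  pulses
}

#' Simulate the full stochastic Kuramoto network
#'
#' Integrates the network with the Euler--Maruyama scheme at step `dt`
#' (default 0.5 ms), optionally under closed-loop phase-locked stimulation.
#' The controller reads the model's own mean phase each step and delivers an
#' instantaneous kick `I_pulse * Z(theta_i)` at upward crossings of the
#' target phase, subject to the refractory rule, during on-epochs only.
#' Reproducible: the same `seed` yields a bit-identical trajectory.
#'
#' When `Z` is the default `-sin` the compiled fast path is used; custom
#' `Z` falls back to a (slow) R loop intended for small problems.
#'
#' @param params a [network_params()]
#' @param protocol a [stim_protocol()] or `NULL` for no stimulation
#' @param duration total simulated time (s), `>= dt`
#' @param dt integration step (s), default 5e-4
#' @param seed integer seed for all randomness (frequencies, initial
#'   phases, dynamics noise)
#' @param theta0 optional initial phases; default drawn uniformly
#' @param omega optional fixed natural frequencies (overrides sampling)
#' @param store_theta keep the full phase matrix (large); default `FALSE`
#' @return object of class `trajectory`: list with `times`, `rho`, `psi`,
#'   `signal` (`rho * cos(psi)`), `pulse_times`, `dt`, `params`,
#'   `protocol`, and optionally `theta`.
#' @export
simulate_network <- function(params, protocol = NULL, duration, dt = 5e-4,
                             seed = NULL, theta0 = NULL, omega = NULL,
                             store_theta = FALSE) {
  if (duration < dt) stop("duration must be >= dt")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(omega)) omega <- sample_natural_frequencies(params)
  if (is.null(theta0)) theta0 <- stats::runif(params$N, -pi, pi)
  n_steps <- round(duration / dt)
  stim <- !is.null(protocol) && protocol$pulse_magnitude > 0
  if (stim) {
    ep <- protocol_epochs(protocol)
    on <- ep[ep$label == "on", , drop = FALSE]
    refractory_s <- protocol$refractory_fraction * 2 * pi / params$omega0
  } else {
    on <- data.frame(start = numeric(0), end = numeric(0))
    refractory_s <- 0
  }
  if (params$z_is_neg_sin || !stim) {
    res <- simulate_kuramoto_cpp(
      theta0, omega, params$K, params$D, dt, n_steps,
      stim, if (stim) protocol$pulse_magnitude else 0,
      if (stim) protocol$target_phase else 0, refractory_s, 1e-6,
      on$start, on$end, store_theta)
  } else {
    res <- simulate_network_r(theta0, omega, params, dt, n_steps,
                              if (stim) protocol else NULL,
                              on, refractory_s, store_theta)
  }
  structure(list(times = res$times, rho = res$rho, psi = res$psi,
                 signal = res$rho * cos(res$psi),
                 pulse_times = res$pulse_times, theta = res$theta,
                 dt = dt, params = params, protocol = protocol),
            class = "trajectory")
}

# Pure-R integrator used only for custom phase-response functions.
simulate_network_r <- function(theta0, omega, params, dt, n_steps,
                               protocol, on, refractory_s, store_theta) {
  N <- length(theta0)
  theta <- theta0
  rho <- numeric(n_steps + 1)
  psi <- numeric(n_steps + 1)
  times <- (0:n_steps) * dt
  th_out <- if (store_theta) matrix(NA_real_, n_steps + 1, N) else NULL
  op <- order_parameter(theta)
  rho[1] <- op$rho; psi[1] <- op$psi
  if (store_theta) th_out[1, ] <- wrap_phase(theta)
  pulses <- numeric(0)
  last <- -Inf
  sn <- sqrt(2 * params$D * dt)
  for (s in seq_len(n_steps)) {
    t <- s * dt
    theta <- theta + dt * (omega + params$K * rho[s] * sin(psi[s] - theta))
    if (params$D > 0) theta <- theta + sn * stats::rnorm(N)
    op <- order_parameter(theta)
    if (!is.null(protocol) && op$rho > 1e-6 && rho[s] > 1e-6 &&
        any(t >= on$start & t <= on$end)) {
      d_prev <- wrap_phase(psi[s] - protocol$target_phase)
      d_cur <- wrap_phase(op$psi - protocol$target_phase)
      if (d_prev < 0 && d_cur >= 0 && (d_cur - d_prev) < pi &&
          (t - last) > refractory_s) {
        theta <- theta + protocol$pulse_magnitude * params$Z(theta)
        op <- order_parameter(theta)
        pulses <- c(pulses, t)
        last <- t
      }
    }
    rho[s + 1] <- op$rho; psi[s + 1] <- op$psi
    if (store_theta) th_out[s + 1, ] <- wrap_phase(theta)
  }
  list(times = times, rho = rho, psi = psi, pulse_times = pulses,
       theta = th_out)
}

#' Observed network activity of a trajectory
#'
#' Observation model `x(t) = rho(t) * cos(psi(t))` — the real part of the
#' order parameter, equal to the population mean of `cos(theta_i)` — plus
#' optional white Gaussian measurement noise.  The oscillation amplitude is
#' proportional to the synchrony, so the Hilbert envelope of `x` tracks
#' `rho`.
#'
#' @param trajectory a [simulate_network()] result
#' @param measurement_noise_sd standard deviation of additive noise
#'   (signal units), default 0
#' @return numeric vector, same length as `trajectory$times`
#' @export
network_signal <- function(trajectory, measurement_noise_sd = 0) {
  x <- trajectory$rho * cos(trajectory$psi)
  if (measurement_noise_sd > 0)
    x <- x + stats::rnorm(length(x), sd = measurement_noise_sd)
  x
}

#' Sample initial phases with a prescribed synchrony
#'
#' Draws phases from the wrapped Cauchy distribution with mean direction
#' `psi` and mean resultant length `rho` — the stationary family of the
#' mean-field reduction — so that the sample order parameter is close to
#' `(rho, psi)` and full/reduced trajectories can be started from matched
#' states.
#'
#' @param n number of phases
#' @param rho target synchrony in `[0, 1)`
#' @param psi target mean phase (rad)
#' @return numeric vector of phases in `[-pi, pi)`
#' @export
init_phases_wrapped_cauchy <- function(n, rho, psi = 0) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  u <- stats::runif(n)
  wrap_phase(psi + 2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5))))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Kuramoto trajectory: %.3g s at dt = %.3g s (%d samples), %d pulses\n  mean rho = %.3f\n",
    max(x$times), x$dt, length(x$times), length(x$pulse_times), mean(x$rho)))
  invisible(x)
}
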