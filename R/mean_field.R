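#' Right-hand side of the reduced (mean-field) model
#'
#' In the infinite-N limit with Cauchy-distributed natural frequencies and
#' per-oscillator response `Z(theta) = -sin(theta)`, the network collapses
#' onto two ODEs for the synchrony `rho` and mean phase `psi`:
#' \deqn{d\rho/dt = -\gamma\rho + (K/2)\rho(1-\rho^2) + (I/2)(1-\rho^2)\cos\psi}
#' \deqn{d\psi/dt = \omega_0 - (I/(2\rho))(1+\rho^2)\sin\psi}
#' The final terms are the instantaneous population amplitude response
#' (ARC) and phase response (PRC) to a drive `I`.
#'
#' @param rho synchrony in `[0, 1]`
#' @param psi mean phase (rad)
#' @param params a [network_params()] (only `omega0`, `gamma`, `K` used)
#' @param I instantaneous drive (rad/s); the PRC term is singular at
#'   `rho = 0`, so `rho = 0` with `I != 0` is an error
#' @return list `(drho, dpsi)`
#' @export
reduced_rhs <- function(rho, psi, params, I = 0) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (rho == 0 && I != 0) stop("PRC term singular at rho = 0 with I != 0")
  drho <- -params$gamma * rho + (params$K / 2) * rho * (1 - rho^2) +
    (I / 2) * (1 - rho^2) * cos(psi)
  dpsi <- params$omega0 -
    if (I == 0) 0 else (I / (2 * rho)) * (1 + rho^2) * sin(psi)
  list(drho = drho, dpsi = dpsi)
}

#' Instantaneous population amplitude response term
#'
#' `(I/2) (1 - rho^2) cos(psi)`: the rate of change of synchrony caused by
#' an instantaneous drive `I` arriving at mean phase `psi`.
#' @inheritParams reduced_rhs
#' @export
instantaneous_arc <- function(rho, psi, I) {
  if (any(rho < 0 | rho > 1)) stop("rho must be in [0, 1]")
  (I / 2) * (1 - rho^2) * cos(psi)
}

#' Instantaneous population phase response term
#'
#' `-(I/(2 rho)) (1 + rho^2) sin(psi)`: the rate of change of the mean
#' phase caused by an instantaneous drive `I` at mean phase `psi`.
#' Singular at `rho = 0`.
#' @inheritParams reduced_rhs
#' @export
instantaneous_prc <- function(rho, psi, I) {
  if (any(rho <= 0 | rho > 1)) stop("rho must be in (0, 1] for the PRC term")
  -(I / (2 * rho)) * (1 + rho^2) * sin(psi)
}

#' Amplitude scaling factor of the stimulation term
#'
#' `(1 - rho^2) / 2`, the synchrony-dependent gain of the instantaneous
#' amplitude response: maximal (0.5) in a fully desynchronized network and
#' zero at complete synchrony, so stimulation of a highly synchronized
#' population cannot change its amplitude further.
#' @param rho synchrony in `[0, 1]` (vectorized)
#' @export
amplitude_scaling <- function(rho) {
  if (any(rho < 0 | rho > 1)) stop("rho must be in [0, 1]")
  (1 - rho^2) / 2
}

#' Noise-free steady-state synchrony
#'
#' Setting the unforced amplitude equation to zero gives the stable branch
#' `rho* = sqrt(1 - 2 gamma / K)` for `K > 2 gamma`, and the incoherent
#' state `rho* = 0` otherwise.
#' @param params a [network_params()]
#' @export
steady_state_rho <- function(params) {
  if (params$K > 2 * params$gamma) sqrt(1 - 2 * params$gamma / params$K) else 0
}

#' Characteristic curve of the network
#'
#' The unforced amplitude drift `drho/dt = -gamma rho + (K/2) rho (1 -
#' rho^2)` evaluated on a synchrony grid.  Its zero crossings are the
#' steady states; its sign shows the network's tendency to synchronize or
#' desynchronize at each amplitude.
#' @param params a [network_params()]
#' @param rho_grid synchrony grid in `[0, 1]`
#' @return data.frame with columns `rho`, `drho_dt`
#' @export
characteristic_curve <- function(params, rho_grid = seq(0, 1, length.out = 101)) {
  if (any(rho_grid < 0 | rho_grid > 1)) stop("rho_grid must lie in [0, 1]")
  data.frame(rho = rho_grid,
             drho_dt = -params$gamma * rho_grid +
               (params$K / 2) * rho_grid * (1 - rho_grid^2))
}

reduced_deriv <- function(rho, psi, gamma, K, omega0) {
  c(-gamma * rho + (K / 2) * rho * (1 - rho^2), omega0)
}

#' Integrate the reduced model with impulsive pulses
#'
#' Fixed-step 4th-order Runge--Kutta integration of the unforced reduced
#' ODEs, with pulses applied as instantaneous jumps
#' `delta rho = (I/2)(1 - rho^2) cos(psi)` and
#' `delta psi = -(I/(2 rho))(1 + rho^2) sin(psi)` — the impulse (dt -> 0)
#' limit of the drive terms, keeping pulse semantics identical to the full
#' model.  Pulses are no-ops while `rho < 1e-6` (mean phase undefined), and
#' `rho` is clipped to `[0, 1]` after each jump (a warning is raised if the
#' excursion exceeds 1e-6).
#'
#' Pulses may be given explicitly via `pulse_times`, or generated closed
#' loop from a `protocol` (target-phase crossings of the running `psi`,
#' with the refractory rule applied when `use_refractory` is `TRUE`).
#'
#' @param rho0,psi0 initial state
#' @param params a [network_params()] (uses `omega0`, `gamma`, `K`)
#' @param duration length of the run (s)
#' @param dt step (s), default 5e-4
#' @param pulse_times optional explicit pulse times (s)
#' @param protocol optional [stim_protocol()] for closed-loop pulses
#' @param I_pulse impulse weight used with `pulse_times` (rad)
#' @param use_refractory apply the refractory rule in closed-loop mode
#' @return list with `times`, `rho`, `psi` (unwrapped), `pulse_times`
#' @export
integrate_reduced <- function(rho0, psi0, params, duration, dt = 5e-4,
                              pulse_times = NULL, protocol = NULL,
                              I_pulse = 0, use_refractory = TRUE) {
  stopifnot(rho0 >= 0, rho0 <= 1)
  n_steps <- round(duration / dt)
  times <- (0:n_steps) * dt
  rho <- psi <- numeric(n_steps + 1)
  rho[1] <- rho0; psi[1] <- psi0
  gamma <- params$gamma; K <- params$K; omega0 <- params$omega0

  closed_loop <- !is.null(protocol)
  if (closed_loop) {
    ep <- protocol_epochs(protocol)
    on <- ep[ep$label == "on", , drop = FALSE]
    refractory_s <- if (use_refractory)
      protocol$refractory_fraction * 2 * pi / params$omega0 else 0
    I_pulse <- protocol$pulse_magnitude
    target <- protocol$target_phase
  }
  sched <- if (!is.null(pulse_times)) sort(pulse_times) else numeric(0)
  next_pulse <- 1L
  last_pulse <- -Inf
  pulses <- numeric(0)
  warned <- FALSE

  for (s in seq_len(n_steps)) {
    r <- rho[s]; p <- psi[s]
    k1 <- reduced_deriv(r, p, gamma, K, omega0)
    k2 <- reduced_deriv(r + dt / 2 * k1[1], p + dt / 2 * k1[2], gamma, K, omega0)
    k3 <- reduced_deriv(r + dt / 2 * k2[1], p + dt / 2 * k2[2], gamma, K, omega0)
    k4 <- reduced_deriv(r + dt * k3[1], p + dt * k3[2], gamma, K, omega0)
    r <- r + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    p <- p + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    t <- s * dt

    fire <- FALSE
    if (!closed_loop) {
      if (next_pulse <= length(sched) && t >= sched[next_pulse] - dt / 2) {
        fire <- TRUE
        next_pulse <- next_pulse + 1L
      }
    } else if (any(t >= on$start & t <= on$end)) {
      d_prev <- wrap_phase(psi[s] - target)
      d_cur <- wrap_phase(p - target)
      fire <- d_prev < 0 && d_cur >= 0 && (d_cur - d_prev) < pi &&
        (t - last_pulse) > refractory_s
    }
    if (fire && r >= 1e-6) {
      dr <- (I_pulse / 2) * (1 - r^2) * cos(p)
      dp <- -(I_pulse / (2 * r)) * (1 + r^2) * sin(p)
      r <- r + dr
      p <- p + dp
      if ((r < -1e-6 || r > 1 + 1e-6) && !warned) {
        warning("pulse jump left [0, 1]; clipping rho")
        warned <- TRUE
      }
      r <- min(max(r, 0), 1)
      pulses <- c(pulses, t)
      last_pulse <- t
    }
    rho[s + 1] <- r; psi[s + 1] <- p
  }
  list(times = times, rho = rho, psi = psi, pulse_times = pulses)
}

# Adaptive Cash--Karp RK45 reference integrator for the unforced reduced
# model; used in tests as an independent oracle for integrate_reduced.
integrate_reduced_ref <- function(rho0, psi0, params, duration,
                                  tol = 1e-9, t_eval = NULL) {
  f <- function(y) reduced_deriv(y[1], y[2], params$gamma, params$K,
                                 params$omega0)
  a <- c(0, 1 / 5, 3 / 10, 3 / 5, 1, 7 / 8)
  b <- list(c(), c(1 / 5), c(3 / 40, 9 / 40), c(3 / 10, -9 / 10, 6 / 5),
            c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
            c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592,
              253 / 4096))
  c5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  c4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)
  t <- 0; y <- c(rho0, psi0); h <- 1e-3
  ts <- t; ys <- matrix(y, 1)
  while (t < duration) {
    h <- min(h, duration - t)
    k <- matrix(0, 6, 2)
    k[1, ] <- f(y)
    for (i in 2:6) {
      yi <- y
      for (j in seq_len(i - 1)) yi <- yi + h * b[[i]][j] * k[j, ]
      k[i, ] <- f(yi)
    }
    y5 <- y + h * colSums(c5 * k)
    y4 <- y + h * colSums(c4 * k)
    err <- max(abs(y5 - y4)) / tol
    if (err <= 1) {
      t <- t + h; y <- y5
      ts <- c(ts, t); ys <- rbind(ys, y)
      h <- h * min(5, 0.9 * err^(-0.2))
    } else {
      h <- h * max(0.1, 0.9 * err^(-0.25))
    }
  }
  if (!is.null(t_eval)) {
    rho <- stats::approx(ts, ys[, 1], xout = t_eval)$y
    psi <- stats::approx(ts, ys[, 2], xout = t_eval)$y
    return(list(times = t_eval, rho = rho, psi = psi))
  }
  list(times = ts, rho = ys[, 1], psi = ys[, 2])
}
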