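#' Simulate a Hodgkin--Huxley neuron with an optional current pulse
#'
#' Forward-Euler integration (default 0.01 ms step) of the classic
#' squid-axon model with the original conductances and rate functions,
#' driven by a constant current `drive` (uA/cm^2).  The default drive of
#' 10 uA/cm^2 produces repetitive spiking at roughly 68 Hz — the precise
#' rate is irrelevant, only the existence of a stable limit cycle is.  An
#' injected square current pulse of width `pulse_width_ms` (default
#' 0.05 ms) can be delivered at `pulse_time_ms`.  Spike times are upward
#' crossings of 0 mV.
#'
#' @param drive constant drive current (uA/cm^2)
#' @param pulse_time_ms pulse onset (ms), `NULL` for none
#' @param pulse_amp pulse amplitude (uA/cm^2)
#' @param pulse_width_ms pulse width (ms), default 0.05
#' @param dt_ms time step (ms), default 0.01
#' @param duration_ms total simulated time (ms)
#' @param return_v also return the membrane-potential trace
#' @return list with `spike_times` (ms), `gating_ok` (logical: gating
#'   variables stayed in `[0, 1]`), and optionally `V`
#' @export
simulate_hh <- function(drive = 10, pulse_time_ms = NULL, pulse_amp = 0,
                        pulse_width_ms = 0.05, dt_ms = 0.01,
                        duration_ms = 500, return_v = FALSE) {
  res <- simulate_hh_cpp(drive,
                         if (is.null(pulse_time_ms)) -1 else pulse_time_ms,
                         pulse_width_ms, pulse_amp, dt_ms, duration_ms,
                         return_v)
  if (length(res$spike_times) == 0)
    warning("no spikes: drive insufficient for repetitive firing")
  res
}

#' Empirical phase response curve of the Hodgkin--Huxley neuron
#'
#' Measures the spike-time shift caused by a brief current pulse delivered
#' at each phase of the firing cycle.  For each phase `phi` on the grid,
#' a pulse is injected at `t_ref + phi / (2 pi) * T` after a reference
#' spike (taken well past the initial transient), and the shift is
#' `(t_next_unperturbed - t_next_perturbed) / T * 2 pi` — positive values
#' are phase advances (earlier spike), negative values delays.  A
#' depolarizing pulse early in the cycle (during the refractory period)
#' delays the next spike, and late in the cycle advances it: the biphasic
#' (type II) response.
#'
#' @param pulse_amp pulse amplitude (uA/cm^2)
#' @param phases phase grid (rad in `[0, 2 pi)`), at least 16 points;
#'   default 24 equally spaced
#' @param drive constant drive current (uA/cm^2)
#' @param pulse_width_ms pulse width (ms)
#' @param dt_ms time step (ms)
#' @param skip_spikes spikes discarded as transient before the reference
#' @return data.frame with columns `phase` (rad) and `shift` (rad)
#' @export
empirical_prc <- function(pulse_amp, phases = seq(0, 2 * pi,
                                                  length.out = 25)[-25],
                          drive = 10, pulse_width_ms = 0.05, dt_ms = 0.01,
                          skip_spikes = 5) {
  if (length(phases) < 16) stop("need at least 16 grid phases")
  base <- simulate_hh(drive, dt_ms = dt_ms, duration_ms = 400)
  sp <- base$spike_times
  if (length(sp) < skip_spikes + 3) stop("not enough spikes for a PRC")
  period <- mean(diff(sp[(skip_spikes):(length(sp))]))
  t_ref <- sp[skip_spikes + 1]
  t_next_unpert <- sp[skip_spikes + 2]
  shifts <- vapply(phases, function(phi) {
    tp <- t_ref + phi / (2 * pi) * period
    pert <- simulate_hh(drive, pulse_time_ms = tp, pulse_amp = pulse_amp,
                        pulse_width_ms = pulse_width_ms, dt_ms = dt_ms,
                        duration_ms = t_next_unpert + 2 * period)
    t_next_pert <- pert$spike_times[pert$spike_times > tp + 1e-9][1]
    if (is.na(t_next_pert)) return(NA_real_)
    (t_next_unpert - t_next_pert) / period * 2 * pi
  }, numeric(1))
  data.frame(phase = phases, shift = shifts)
}
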