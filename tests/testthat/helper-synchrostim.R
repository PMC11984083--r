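# Shared fixtures, built in code.

tone_recording <- function(f = 30, fs = 2000, duration = 10, amp = 1,
                           phase = 0) {
  t <- (0:(duration * fs - 1)) / fs
  recording(amp * cos(2 * pi * f * t + phase), fs)
}

# Analytic-band stub with a prescribed envelope/phase (for estimator units)
analytic_stub <- function(envelope = NULL, phase_unwrapped = NULL, fs = 2000) {
  n <- max(length(envelope), length(phase_unwrapped))
  if (is.null(envelope)) envelope <- rep(1, n)
  if (is.null(phase_unwrapped)) phase_unwrapped <- rep(0, n)
  structure(list(envelope = envelope, phase = wrap_phase(phase_unwrapped),
                 phase_unwrapped = phase_unwrapped, fs = fs, band = NULL,
                 pulse_times = numeric(0), epochs = NULL),
            class = "analytic_band")
}

# two-oscillator-free default params for quick simulations
quick_params <- function(N = 50, K = 4 * 2 * pi, D = pi, gamma = 2 * pi,
                         omega0 = 2 * pi * 30) {
  network_params(omega0, gamma, K, D, N)
}
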