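#' Single-channel recording container
#'
#' Holds a sampled voltage-like series with its sample rate, pulse-time
#' annotations, and labeled epochs.  Times are in seconds from the first
#' sample (sample `k` is at time `(k - 1) / fs`).
#'
#' @param samples numeric vector
#' @param fs sample rate (Hz), `> 0`
#' @param pulse_times pulse annotation times (s), within the record
#' @param epochs optional data.frame with columns `start`, `end`, `label`
#'   (`"off"`/`"on"`) and optionally `target_phase`; must be ordered and
#'   non-overlapping
#' @return object of class `recording`
#' @export
recording <- function(samples, fs, pulse_times = numeric(0), epochs = NULL) {
  if (fs <= 0) stop("fs must be > 0")
  dur <- (length(samples) - 1) / fs
  if (length(pulse_times) && (min(pulse_times) < 0 || max(pulse_times) > dur))
    stop("pulse_times must lie within the record")
  if (!is.null(epochs)) {
    stopifnot(all(c("start", "end", "label") %in% names(epochs)))
    if (is.unsorted(epochs$start) || any(epochs$end <= epochs$start))
      stop("epochs must be ordered with end > start")
    if (nrow(epochs) > 1 &&
        any(epochs$start[-1] < epochs$end[-nrow(epochs)] - 1e-9))
      stop("epochs must not overlap")
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 pulse_times = sort(pulse_times), epochs = epochs),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Recording: %d samples at %g Hz (%.2f s), %d pulses, %s epochs\n",
              length(x$samples), x$fs, (length(x$samples) - 1) / x$fs,
              length(x$pulse_times),
              if (is.null(x$epochs)) "no" else nrow(x$epochs)))
  invisible(x)
}

rec_times <- function(rec) (seq_along(rec$samples) - 1) / rec$fs

## ---- Butterworth design (bilinear transform) --------------------------

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rk in r) p <- c(p, 0) - c(0, p * rk)
  p
}

# Digital Butterworth coefficients via analog prototype + bilinear
# transform (matched against scipy.signal.butter).
butter_coeffs <- function(order, low, high = NULL, fs,
                          type = c("band", "low", "high")) {
  type <- match.arg(type)
  fs2 <- 2 * fs
  warp <- function(f) fs2 * tan(pi * f / fs)
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP prototype poles
  if (type == "low") {
    wc <- warp(low)
    p <- p * wc
    z <- complex(0)
    gain <- wc^order
  } else if (type == "high") {
    wc <- warp(low)
    p <- wc / p
    z <- rep(0 + 0i, order)
    gain <- 1  # normalized at Nyquist below
  } else {
    wl <- warp(low); wh <- warp(high)
    bw <- wh - wl; w0 <- sqrt(wl * wh)
    gain <- bw^order
    ps <- p * bw / 2
    p <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
    z <- rep(0 + 0i, order)
  }
  # bilinear transform
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  if (type == "low") {
    g <- sum(b) / sum(a)  # force unity DC gain
    b <- b / g
  } else if (type == "band") {
    w <- 2 * pi * sqrt(low * high) / fs
    g <- Mod(filter_gain_ba(b, a, w))
    b <- b / g
  } else {
    w <- pi  # unity at Nyquist
    g <- Mod(filter_gain_ba(b, a, w))
    b <- b / g
  }
  list(b = b, a = a)
}

filter_gain_ba <- function(b, a, w) {
  e <- exp(-1i * w * (seq_along(b) - 1))
  num <- sum(b * e)
  e <- exp(-1i * w * (seq_along(a) - 1))
  num / sum(a * e)
}

#' Frequency response magnitude of a designed filter
#' @param coeffs list with `b`, `a`
#' @param f frequencies (Hz, vectorized)
#' @param fs sample rate (Hz)
#' @return magnitude of the transfer function at `f`
#' @export
filter_gain <- function(coeffs, f, fs) {
  vapply(2 * pi * f / fs,
         function(w) Mod(filter_gain_ba(coeffs$b, coeffs$a, w)), numeric(1))
}

# Zero-phase (forward-backward) filtering with odd-reflection padding.
filtfilt_ba <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1, max(3 * (max(length(a), length(b)) - 1), 200))
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  y <- c(pre, x, post)
  y <- iir_filter_cpp(b, a, y)
  y <- rev(iir_filter_cpp(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

## ---- Conditioning chain ----------------------------------------------

#' Interpolate stimulation artifacts
#'
#' Replaces the samples in `[pulse, pulse + post_ms]` around every
#' annotated pulse by linear interpolation between the last clean sample
#' before the pulse and the first clean sample after the window.  Windows
#' running past the record end are truncated with a warning.
#'
#' @param rec a [recording()] with pulse annotations
#' @param post_ms window length after pulse onset (ms), default 1.5
#' @return a [recording()] with interpolated samples
#' @export
remove_artifacts <- function(rec, post_ms = 1.5) {
  x <- rec$samples
  n <- length(x)
  t <- rec_times(rec)
  for (tp in rec$pulse_times) {
    ia <- max(1L, sum(t < tp - 1e-12))
    ib_cand <- which(t > tp + post_ms / 1000 + 1e-12)
    if (length(ib_cand) == 0) {
      warning("artifact window exceeds record end; truncating")
      if (ia < n) x[(ia + 1):n] <- x[ia]
      next
    }
    ib <- ib_cand[1]
    if (ib - ia > 1) {
      idx <- (ia + 1):(ib - 1)
      x[idx] <- x[ia] + (x[ib] - x[ia]) * (idx - ia) / (ib - ia)
    }
  }
  recording(x, rec$fs, rec$pulse_times, rec$epochs)
}

#' Downsample with anti-aliasing
#'
#' Low-pass filters (zero-phase 8th-order Butterworth, cutoff at 80% of
#' the new Nyquist frequency) and decimates by the integer ratio
#' `fs / target_fs`.  Pulse-time and epoch annotations, being in seconds,
#' are unchanged.
#'
#' @param rec a [recording()]
#' @param target_fs target sample rate (Hz); `fs / target_fs` must be an
#'   integer
#' @return a [recording()] at `target_fs`
#' @export
downsample <- function(rec, target_fs = 2000) {
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9) stop("fs / target_fs must be an integer")
  q <- round(q)
  if (q == 1) return(rec)
  co <- butter_coeffs(8, 0.8 * target_fs / 2, fs = rec$fs, type = "low")
  y <- filtfilt_ba(co$b, co$a, rec$samples)
  recording(y[seq(1, length(y), by = q)], target_fs, rec$pulse_times,
            rec$epochs)
}

#' Zero-phase Butterworth band-pass
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase), so the estimated Hilbert phase downstream carries no
#' group-delay bias; the effective magnitude order is doubled.
#'
#' @param rec a [recording()] or numeric vector (then `fs` is required)
#' @param band numeric length-2 `(low, high)` in Hz, `0 < low < high <
#'   fs/2`; default `c(20, 35)` (high-beta)
#' @param order filter order, default 4
#' @param fs sample rate when `rec` is a bare vector
#' @return same type as `rec`, filtered; recordings carry a `band`
#'   attribute
#' @export
bandpass <- function(rec, band = c(20, 35), order = 4, fs = NULL) {
  bare <- !inherits(rec, "recording")
  x <- if (bare) rec else rec$samples
  fsr <- if (bare) fs else rec$fs
  if (is.null(fsr)) stop("fs required for bare vectors")
  if (!(band[1] > 0 && band[2] > band[1] && band[2] < fsr / 2))
    stop("need 0 < low < high < fs/2")
  co <- butter_coeffs(order, band[1], band[2], fs = fsr, type = "band")
  y <- filtfilt_ba(co$b, co$a, x)
  if (bare) return(y)
  out <- recording(y, fsr, rec$pulse_times, rec$epochs)
  attr(out, "band") <- band
  out
}

#' Analytic signal: envelope and instantaneous phase
#'
#' Hilbert transform (FFT method) of a band-limited signal.  The envelope
#' is the magnitude and the phase the angle of the analytic signal; an
#' unwrapped phase view is included.  The first and last 0.5 s suffer edge
#' effects and are excluded by the downstream estimators.
#'
#' @param rec a [recording()] (typically the output of [bandpass()]) or a
#'   numeric vector with `fs` supplied
#' @param fs sample rate for bare vectors
#' @return object of class `analytic_band`: list with `envelope`, `phase`
#'   (wrapped), `phase_unwrapped`, `fs`, `band`, `pulse_times`, `epochs`
#' @export
analytic <- function(rec, fs = NULL) {
  bare <- !inherits(rec, "recording")
  x <- if (bare) rec else rec$samples
  fsr <- if (bare) fs else rec$fs
  z <- hilbert_analytic(x)
  ph <- Arg(z)
  structure(list(envelope = Mod(z), phase = ph,
                 phase_unwrapped = unwrap_phase(ph), fs = fsr,
                 band = if (bare) NULL else attr(rec, "band"),
                 pulse_times = if (bare) numeric(0) else rec$pulse_times,
                 epochs = if (bare) NULL else rec$epochs),
            class = "analytic_band")
}

hilbert_analytic <- function(x) {
  # pad by mirror reflection to a 2-3-5-smooth length: R's mixed-radix FFT
  # is quadratic on awkward prime factors, and a time-reversed extension
  # stays in-band (unlike zero or point-reflection padding)
  n0 <- length(x)
  nfft <- stats::nextn(n0, c(2, 3, 5))
  if (nfft > n0) {
    pad <- nfft - n0
    x <- c(x, x[(n0 - 1):(n0 - pad)])
  }
  z <- hilbert_analytic_core(x)
  z[seq_len(n0)]
}

hilbert_analytic_core <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Unwrap a wrapped phase series
#' @param p phases (rad)
#' @export
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  p[1] + c(0, cumsum(wrap_phase(diff(p))))
}

## ---- Spectra and dynamic features -------------------------------------

#' Welch power spectral density
#'
#' Hann-windowed (periodic window) segment averaging with 50% overlap and
#' per-segment mean removal; one-sided density scaling, so that
#' `sum(psd) * df` approximates the signal variance.
#'
#' @param x numeric vector
#' @param fs sample rate (Hz)
#' @param resolution frequency resolution (Hz): segment length is
#'   `fs / resolution` samples; default 1
#' @return data.frame with columns `freq` (0..fs/2) and `density`
#' @export
welch_psd <- function(x, fs, resolution = 1) {
  nper <- round(fs / resolution)
  if (length(x) < nper) stop("signal shorter than one Welch segment")
  step <- floor(nper / 2)
  starts <- seq(1, length(x) - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nper - 1)) / nper)
  scale <- fs * sum(w^2)
  nf <- floor(nper / 2) + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nper - 1)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg)[1:nf])^2 / scale
    P[2:(nf - 1)] <- 2 * P[2:(nf - 1)]
    if (nper %% 2 == 1) P[nf] <- 2 * P[nf]
    acc <- acc + P
  }
  data.frame(freq = (0:(nf - 1)) * fs / nper, density = acc / length(starts))
}

#' Dynamic features of an oscillatory signal
#'
#' The three feature sets used for model fitting: the Welch PSD of the
#' z-scored signal, the probability density of its Hilbert envelope
#' (64 equal-width bins on `[0, env_max]`, overflow clipped into the top
#' bin so the density always integrates to 1), and the Welch PSD of the
#' mean-removed envelope.  The first/last `edge_trim` seconds of the
#' envelope are excluded (Hilbert edge effects).  Because the signal is
#' z-scored first, the features are invariant to affine rescaling of the
#' raw signal.
#'
#' @param signal numeric vector (assumed band-limited) or a [recording()]
#' @param fs sample rate (Hz); ignored for recordings
#' @param psd_resolution PSD resolution (Hz), default 1
#' @param env_max upper edge of the envelope histogram; default the
#'   maximum of this signal's own (trimmed) envelope.  Pass the data
#'   features' `env_max` when building model features so the grids match.
#' @param n_bins number of envelope bins, default 64
#' @param edge_trim seconds trimmed from each end of the envelope
#' @return object of class `dynamic_features` with elements `signal_psd`,
#'   `env_pdf` (columns `mid`, `density`, plus `breaks` attribute),
#'   `env_psd`, `env_max`, `fs`, `psd_resolution`
#' @export
dynamic_features <- function(signal, fs = NULL, psd_resolution = 1,
                             env_max = NULL, n_bins = 64, edge_trim = 0.5) {
  if (inherits(signal, "recording")) {
    fs <- signal$fs
    signal <- signal$samples
  }
  if (length(signal) < 2 * fs) stop("signal must be at least 2 s long")
  s <- stats::sd(signal)
  if (s == 0) stop("constant signal")
  x <- (signal - mean(signal)) / s
  spsd <- welch_psd(x, fs, psd_resolution)
  env <- Mod(hilbert_analytic(x))
  k <- round(edge_trim * fs)
  if (2 * k + fs > length(env)) k <- 0
  env <- env[(k + 1):(length(env) - k)]
  if (is.null(env_max)) env_max <- max(env)
  breaks <- seq(0, env_max, length.out = n_bins + 1)
  ec <- pmin(env, env_max - 1e-12 * env_max)
  h <- graphics::hist(ec, breaks = breaks, plot = FALSE)
  epdf <- data.frame(mid = h$mids, density = h$density)
  attr(epdf, "breaks") <- breaks
  epsd <- welch_psd(env - mean(env), fs, psd_resolution)
  structure(list(signal_psd = spsd, env_pdf = epdf, env_psd = epsd,
                 env_max = env_max, fs = fs,
                 psd_resolution = psd_resolution),
            class = "dynamic_features")
}

#' @export
print.dynamic_features <- function(x, ...) {
  pk <- x$signal_psd$freq[which.max(x$signal_psd$density)]
  cat(sprintf(
    "Dynamic features: PSD grid 0-%g Hz at %g Hz (peak %g Hz), %d envelope bins on [0, %.3g]\n",
    max(x$signal_psd$freq), x$psd_resolution, pk,
    nrow(x$env_pdf), x$env_max))
  invisible(x)
}

## ---- File interfaces ---------------------------------------------------

#' Write / read a recording as plain text
#'
#' Columnar TSV with a JSON header line (prefixed `#`) carrying `fs`,
#' pulse times, and epochs; round-trips losslessly at full double
#' precision.
#' @param rec a [recording()]
#' @param path file path
#' @export
write_recording <- function(rec, path) {
  hdr <- jsonlite::toJSON(list(fs = rec$fs, pulse_times = rec$pulse_times,
                               epochs = rec$epochs),
                          digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  writeLines(format(rec$samples, digits = 17, trim = TRUE, scientific = TRUE),
             con)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  ep <- hdr$epochs
  if (!is.null(ep) && !is.data.frame(ep)) ep <- as.data.frame(ep)
  recording(as.numeric(lines[-1]), as.numeric(hdr$fs),
            if (is.null(hdr$pulse_times)) numeric(0)
            else as.numeric(hdr$pulse_times),
            ep)
}
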