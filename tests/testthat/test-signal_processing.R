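test_that("Butterworth design reproduces independently computed gains", {
  # reference magnitudes computed with scipy.signal.butter/freqz
  co <- synchrostim:::butter_coeffs(4, 20, 35, fs = 2000, type = "band")
  g <- filter_gain(co, c(10, 27, 70), 2000)
  expect_equal(g[1], 0.00391343, tolerance = 2e-4)
  expect_equal(g[2], 0.99995424, tolerance = 2e-4)
  expect_equal(g[3], 0.00385580, tolerance = 2e-4)
  co2 <- synchrostim:::butter_coeffs(8, 800, fs = 20000, type = "low")
  g2 <- filter_gain(co2, c(400, 800, 1500), 20000)
  expect_equal(g2[1], 0.99999284, tolerance = 1e-5)
  expect_equal(g2[2], sqrt(0.5), tolerance = 1e-5)
  expect_equal(g2[3], 0.00587757, tolerance = 1e-5)
})

test_that("artifact interpolation is exact on ramps and flats", {
  fs <- 2000
  t <- (0:(fs - 1)) / fs
  # no pulses: identity
  rec0 <- recording(sin(t), fs)
  expect_identical(remove_artifacts(rec0)$samples, rec0$samples)
  # flat signal with a spike inside the pulse window
  x <- rep(2, fs)
  x[round(0.5 * fs) + 2] <- 50
  rec <- recording(x, fs, pulse_times = 0.5)
  expect_equal(remove_artifacts(rec)$samples, rep(2, fs))
  # ramp: interpolated samples fall exactly on the ramp
  ramp <- recording(3 * t + 1, fs, pulse_times = 0.5)
  expect_equal(remove_artifacts(ramp)$samples, 3 * t + 1, tolerance = 1e-12)
  # window beyond record end: truncated with warning
  late <- recording(3 * t + 1, fs, pulse_times = t[fs] - 2e-4)
  expect_warning(remove_artifacts(late), "truncat")
})

test_that("downsampling preserves the passband and kills aliases", {
  fs <- 20000
  t <- (0:(4 * fs - 1)) / fs
  rec <- recording(cos(2 * pi * 30 * t), fs, pulse_times = 1.5)
  dn <- downsample(rec, 2000)
  expect_equal(dn$fs, 2000)
  expect_equal(dn$pulse_times, 1.5)
  i <- seq_along(dn$samples) > 1000 & seq_along(dn$samples) < 7000
  expect_lt(max(abs(dn$samples[i] - cos(2 * pi * 30 * (which(i) - 1) / 2000))),
            0.01)
  # 1500 Hz tone: > 40 dB down after anti-aliasing
  hi <- downsample(recording(cos(2 * pi * 1500 * t), fs), 2000)
  expect_lt(sd(hi$samples[1000:7000]), sqrt(0.5) * 10^(-40 / 20))
  expect_identical(downsample(rec, 20000), rec)
  expect_error(downsample(rec, 1500), "integer")
})

test_that("zero-phase band-pass keeps in-band tones and removes DC", {
  fs <- 2000
  t <- (0:(6 * fs - 1)) / fs
  x <- 1.4 * cos(2 * pi * 27 * t) + 5
  rec <- bandpass(recording(x, fs), c(20, 35))
  i <- t > 1 & t < 5
  # center-frequency amplitude preserved within 2 %, phase shift ~ 0
  expect_lt(max(abs(rec$samples[i] - 1.4 * cos(2 * pi * 27 * t[i]))),
            0.02 * 1.4)
  expect_lt(abs(mean(rec$samples)), 1e-3)   # DC removed
  # out-of-band tone at twice the upper edge: >= 20 dB down
  y <- bandpass(recording(cos(2 * pi * 70 * t), fs), c(20, 35))
  expect_lt(sd(y$samples[i]), sqrt(0.5) * 10^(-20 / 20))
  expect_error(bandpass(recording(x, fs), c(0, 35)), "fs/2|low")
})

test_that("band-pass is idempotent on band-limited input", {
  # input concentrated well inside the passband (content in the
  # transition bands is legitimately attenuated again by a second pass)
  fs <- 2000
  t <- (0:(6 * fs - 1)) / fs
  set.seed(4)
  x <- cos(2 * pi * 26 * t + 1) + 0.8 * cos(2 * pi * 28 * t) +
    0.5 * cos(2 * pi * 30 * t + 2)
  once <- bandpass(recording(x, fs))
  twice <- bandpass(once)
  i <- 2000:10000
  expect_lt(max(abs(twice$samples[i] - once$samples[i])),
            0.01 * sd(once$samples[i]))
})

test_that("analytic signal recovers envelope and instantaneous phase", {
  fs <- 2000
  t <- (0:(10 * fs - 1)) / fs
  ab <- analytic(bandpass(recording(0.8 * cos(2 * pi * 30 * t), fs)))
  i <- t > 0.5 & t < 9.5
  expect_lt(max(abs(ab$envelope[i] - 0.8)), 0.008)
  rate <- mean(diff(ab$phase_unwrapped[i])) * fs / (2 * pi)
  expect_equal(rate, 30, tolerance = 1e-3)
  # slow amplitude modulation is tracked (Bedrosian regime)
  am <- (1 + 0.3 * sin(2 * pi * 1.1 * t)) * cos(2 * pi * 30 * t)
  ab2 <- analytic(am, fs = fs)
  expect_lt(max(abs(ab2$envelope[i] - (1 + 0.3 * sin(2 * pi * 1.1 * t[i])))),
            0.02 * 1.3)
})

test_that("unwrap reverses wrapping", {
  ph <- cumsum(runif(500, 0, 0.5))
  expect_equal(unwrap_phase(wrap_phase(ph)), ph - ph[1] + wrap_phase(ph[1]))
})

test_that("Welch PSD integrates to the variance and localizes tones", {
  fs <- 2000
  set.seed(11)
  x <- rnorm(20 * fs)
  psd <- welch_psd(x, fs)
  expect_true(all(psd$density >= 0))
  expect_equal(sum(psd$density) * 1, var(x), tolerance = 0.05)
  # flat within Welch variance bounds: compare band means
  m1 <- mean(psd$density[psd$freq > 100 & psd$freq < 400])
  m2 <- mean(psd$density[psd$freq > 600 & psd$freq < 900])
  expect_lt(abs(m1 / m2 - 1), 0.1)
  tone <- welch_psd(cos(2 * pi * 30 * (0:(10 * fs - 1)) / fs), fs)
  expect_equal(tone$freq[which.max(tone$density)], 30)
})

test_that("dynamic features have the documented structure", {
  rec <- tone_recording(30, duration = 10)
  ft <- dynamic_features(rec)
  bw <- diff(attr(ft$env_pdf, "breaks"))[1]
  expect_equal(sum(ft$env_pdf$density) * bw, 1, tolerance = 1e-6)
  expect_equal(ft$signal_psd$freq[which.max(ft$signal_psd$density)], 30)
  # constant-envelope tone: envelope mass concentrated in one bin
  expect_gt(max(ft$env_pdf$density) * bw, 0.95)
  expect_true(all(ft$signal_psd$density >= 0) && all(ft$env_psd$density >= 0))
  expect_error(dynamic_features(rnorm(100), fs = 2000), "2 s")
})

test_that("features are invariant to affine rescaling of the raw signal", {
  p <- quick_params(N = 60)
  tr <- simulate_network(p, NULL, 6, seed = 2)
  f1 <- dynamic_features(tr$signal, 2000)
  f2 <- dynamic_features(7 * tr$signal + 3, 2000)
  expect_equal(f1$signal_psd$density, f2$signal_psd$density, tolerance = 1e-10)
  expect_equal(f1$env_pdf$density, f2$env_pdf$density, tolerance = 1e-10)
  expect_equal(f1$env_psd$density, f2$env_psd$density, tolerance = 1e-10)
})

test_that("recordings round-trip through the text format losslessly", {
  p <- quick_params(N = 20)
  tr <- simulate_network(p, NULL, 1.2, seed = 6)
  ep <- data.frame(start = c(0, 0.5), end = c(0.5, 1.1),
                   label = c("off", "on"), target_phase = c(NA, 1.2))
  rec <- recording(tr$signal, 2000, pulse_times = c(0.6, 0.9), epochs = ep)
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$samples, rec$samples)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$pulse_times, rec$pulse_times)
  expect_equal(back$epochs$start, ep$start)
  unlink(path)
})
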