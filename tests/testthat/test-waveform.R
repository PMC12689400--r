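test_that("waveform_record enforces its invariants", {
  t <- seq(0, 1, by = 0.005)
  n <- length(t)
  expect_s3_class(waveform_record(t, rep(1, n), rep(0, n)), "waveform_record")
  # jittered time
  tj <- t; tj[10] <- tj[10] + 0.002
  expect_error(waveform_record(tj, rep(1, n), rep(0, n)),
               class = "aprv_nonuniform_time")
  expect_error(waveform_record(t, rep(1, n - 1), rep(0, n)),
               class = "aprv_invalid_input")
  expect_error(waveform_record(t, rep(1, n), rep(0, n),
                               phase = rep("breathing", n)),
               class = "aprv_invalid_input")
  # sample rate inferred from the time step
  expect_equal(waveform_record(t, rep(1, n), rep(0, n))$sample_rate, 200)
})

test_that("low-pass filter preserves DC and zero signals", {
  rec <- flat_record(n = 400, pressure = 10, flow = 0)
  out <- lowpass_filter(rec, cutoff_hz = 20)
  expect_equal(out$pressure, rec$pressure, tolerance = 1e-8)
  expect_equal(out$flow, rep(0, 400))
  expect_identical(out$time, rec$time)
})

test_that("filter attenuation matches the designed transfer function", {
  fs <- 200; f0 <- 50; cutoff <- 10
  t <- (0:(8 * fs)) / fs
  rec <- waveform_record(t, pressure = sin(2 * pi * f0 * t),
                         flow = rep(0, length(t)))
  out <- lowpass_filter(rec, cutoff)
  # oracle: squared magnitude (forward-backward) of the designed biquad at f0
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  z <- exp(-2i * pi * f0 / fs)
  H <- sum(bf$b * z^(0:2)) / sum(bf$a * z^(0:2))
  expected_gain <- Mod(H)^2
  mid <- out$pressure[(2 * fs):(6 * fs)]
  measured_gain <- sqrt(mean(mid^2)) * sqrt(2)
  expect_lt(abs(measured_gain - expected_gain), 0.05 * expected_gain + 1e-6)
})

test_that("filtering is idempotent on signals band-limited below cutoff", {
  fs <- 200
  t <- (0:(10 * fs)) / fs
  x <- 5 + 0.5 * sin(2 * pi * 0.05 * t)
  rec <- waveform_record(t, pressure = x, flow = x / 10)
  once <- lowpass_filter(rec, 20)
  twice <- lowpass_filter(once, 20)
  expect_lt(max(abs(twice$pressure - once$pressure)) / max(abs(once$pressure)),
            1e-9)
})

test_that("filter rejects cutoffs at or beyond Nyquist", {
  rec <- flat_record(fs = 200)
  expect_error(lowpass_filter(rec, 100), class = "aprv_invalid_parameter")
  expect_error(lowpass_filter(rec, 150), class = "aprv_invalid_parameter")
  expect_error(lowpass_filter(rec, 0), class = "aprv_invalid_parameter")
})

test_that("volume integration is exact for constant flow and zero flow", {
  fs <- 200
  t <- (0:(2 * fs)) / fs
  rec <- waveform_record(t, rep(0, length(t)), rep(0.5, length(t)))
  rec <- integrate_volume(rec, reset_indices = 1)
  expect_equal(rec$volume[length(t)], 1.0, tolerance = 1e-12)
  rec0 <- integrate_volume(flat_record(), reset_indices = 1)
  expect_identical(rec0$volume, rep(0, 100))
})

test_that("volume integration matches the closed-form antiderivative", {
  fs <- 200
  t <- (0:fs) / fs  # one period of sin(2 pi t)
  rec <- waveform_record(t, rep(0, length(t)), sin(2 * pi * t))
  rec <- integrate_volume(rec, reset_indices = 1)
  expect_lt(max(abs(rec$volume - (1 - cos(2 * pi * t)) / (2 * pi))), 1e-4)
})

test_that("volume integration is linear in flow and resets per breath", {
  fs <- 200
  t <- (0:(2 * fs)) / fs
  f <- sin(2 * pi * t) + 0.3
  r1 <- integrate_volume(waveform_record(t, t * 0, f), 1)
  r3 <- integrate_volume(waveform_record(t, t * 0, 3 * f), 1)
  expect_equal(r3$volume, 3 * r1$volume, tolerance = 1e-12)
  # reset zeroes the volume at each reset index
  rr <- integrate_volume(waveform_record(t, t * 0, f), c(1, fs + 1))
  expect_identical(rr$volume[fs + 1], 0)
  expect_error(integrate_volume(waveform_record(t, t * 0, f), integer(0)),
               class = "aprv_invalid_input")
})

test_that("breath segmentation recovers the configured durations", {
  s <- cd_settings(t_low = 0.5, rise = 0)
  cfg <- simulation_config(s, lung = test_lung(), n_cycles = 1, dt = 0.005)
  rec <- simulate_aprv(cfg)
  rec$phase <- NULL  # force threshold detection
  seg <- segment_breaths(rec, s)
  expect_equal(nrow(seg), 1)
  expect_lt(abs(seg$t_high_measured - 4.0), 1 / rec$sample_rate + 1e-9)
  expect_lt(abs(seg$t_low_measured - 0.5), 1 / rec$sample_rate + 1e-9)

  cfg5 <- simulation_config(s, lung = test_lung(), n_cycles = 5, dt = 0.005)
  rec5 <- simulate_aprv(cfg5)
  rec5$phase <- NULL
  expect_equal(nrow(segment_breaths(rec5, s)), 5)
})

test_that("constant pressure yields no segments and a warning, not an error", {
  s <- cd_settings()
  expect_warning(seg <- segment_breaths(flat_record(pressure = 10), s),
                 class = "aprv_no_crossings")
  expect_equal(nrow(seg), 0)
})

test_that("phase-channel segmentation agrees with threshold detection", {
  s <- cd_settings(t_low = 0.6, rise = 0)
  cfg <- simulation_config(s, lung = test_lung(), n_cycles = 3, dt = 0.005)
  rec <- simulate_aprv(cfg)
  by_phase <- segment_breaths(rec, s)
  rec2 <- rec; rec2$phase <- NULL
  by_threshold <- segment_breaths(rec2, s)
  expect_equal(nrow(by_phase), nrow(by_threshold))
  expect_true(all(abs(by_phase$start_index - by_threshold$start_index) <= 1))
  expect_true(all(abs(by_phase$insp_end_index - by_threshold$insp_end_index) <= 1))
})
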