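# The synthetic generator: determinism, construction guarantees, spectra.

test_that("identical seeds give bit-identical recordings", {
  cfg <- synthetic_config(n_channels = 2, duration = 30, seed = 101)
  g1 <- generate_sleep_recording(cfg)
  g2 <- generate_sleep_recording(cfg)
  expect_identical(g1$recording$data, g2$recording$data)
  expect_identical(g1$ground_truth$channels, g2$ground_truth$channels)
  g3 <- generate_sleep_recording(synthetic_config(n_channels = 2, duration = 30,
                                                  seed = 102))
  expect_false(identical(g1$recording$data, g3$recording$data))
})

test_that("config validation names the offending field", {
  expect_error(synthetic_config(so_band = c(4, 0.5)), "so_band")
  expect_error(synthetic_config(coupling_depth = 1.4), "coupling_depth")
  expect_error(synthetic_config(fs = 128, gamma_band = band_definition(90, 40)),
               "gamma_band")
  expect_error(synthetic_config(duration = 0), "duration")
})

test_that("ground truth records every slow-oscillation draw inside the recording", {
  cfg <- synthetic_config(n_channels = 3, duration = 60, seed = 5)
  g <- generate_sleep_recording(cfg)
  for (ch in g$ground_truth$channels) {
    ev <- ch$so_events
    expect_true(all(ev$onset >= 0 & ev$onset + ev$duration <= 60))
    expect_true(all(ev$n_cycles <= cfg$max_consecutive_so_cycles))
    expect_true(all(ev$freq >= cfg$so_band[1] & ev$freq <= cfg$so_band[2]))
    # unitary events: gaps exist, events do not overlap
    expect_true(all(diff(ev$onset) >= ev$duration[-nrow(ev)]))
  }
})

test_that("slow-oscillation spectrum is broadband with no narrow peak", {
  cfg <- synthetic_config(n_channels = 1, duration = 240, spindle_amp = 0,
                          gamma_amp = 0, noise_amp = 0, seed = 33)
  g <- generate_sleep_recording(cfg)
  x <- g$recording$data[, 1]
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x))[seq_len(n %/% 2)])^2
  freqs <- (seq_len(n %/% 2) - 1) * cfg$fs / n
  inband <- freqs >= 0.5 & freqs <= 4
  # smooth to 0.1 Hz resolution before the peakedness check
  f_grid <- seq(0.5, 4, by = 0.1)
  sm <- vapply(f_grid, function(f)
    mean(spec[inband & abs(freqs - f) <= 0.05]), numeric(1))
  for (i in seq_along(f_grid)) {
    oct_lo <- f_grid[i] / 2; oct_hi <- f_grid[i] * 2
    nb <- freqs >= max(0.4, oct_lo) & freqs <= min(4.5, oct_hi) &
      abs(freqs - f_grid[i]) > 0.05
    expect_lt(sm[i], 3 * mean(spec[nb]) + 1e-12)
  }
})

test_that("acoustic trigger trains follow the block arithmetic", {
  expect_length(generate_acoustic_triggers(1, 300), 300)
  expect_length(generate_acoustic_triggers(0.75, 300), 225)
  expect_length(generate_acoustic_triggers(1, 0), 0)
  t0 <- generate_acoustic_triggers(1, 10)
  expect_equal(diff(t0), rep(1, 9))
  tj <- generate_acoustic_triggers(1, 300, jitter = 0.05, seed = 4)
  expect_length(tj, 300)
  expect_gt(sd(diff(tj)), 0)
  expect_identical(tj, generate_acoustic_triggers(1, 300, jitter = 0.05, seed = 4))
})

test_that("injected tACS artifact dominates at the requested ratio and round-trips", {
  cfg <- synthetic_config(n_channels = 1, duration = 60, coupling_depth = 0,
                          gamma_amp = 0, seed = 55)
  g <- generate_sleep_recording(cfg)
  neural <- g$recording$data[, 1]
  rms <- sd(neural)
  rec2 <- inject_tacs_artifact(g$recording, f_stim = 1,
                               amplitude = sqrt(2) * 10 * rms)
  artifact <- rec2$data[, 1] - neural
  expect_gte(sd(artifact) / rms, 10)
  # f_stim = 1 Hz, 60 s -> exactly 60 artifact periods, counted by the
  # package's own cycle segmentation of the fitted stimulation phase
  fit <- fit_harmonic_artifact(artifact, rec2$fs, 1)
  ph <- stimulation_phase(fit, (seq_len(60 * rec2$fs) - 1) / rec2$fs)
  expect_identical(nrow(segment_cycles(phase = ph, fs = rec2$fs,
                                       phase_source = "tacs")), 60L)
  # round trip: harmonic fit residual is tiny relative to the artifact
  res <- subtract_artifact(artifact, fit)
  expect_lt(sqrt(mean(res^2)) / sd(artifact), 0.01)
  expect_error(inject_tacs_artifact(g$recording, 1, 100,
                                    harmonic_coeffs = data.frame(k = 300, a = 1, b = 0)),
               "Nyquist")
})

test_that("outlier epochs scale broadband power and are merged when overlapping", {
  cfg <- synthetic_config(n_channels = 1, duration = 30, seed = 9)
  g <- generate_sleep_recording(cfg)
  same <- inject_outlier_epochs(g$recording,
                                data.frame(onset = 5, duration = 2), gain = 1)
  expect_equal(same$data, g$recording$data, tolerance = 1e-12)
  up <- inject_outlier_epochs(g$recording,
                              data.frame(onset = 5, duration = 2), gain = 10)
  i <- (5 * 512 + 1):(7 * 512)
  expect_equal(mean(up$data[i, 1]^2) / mean(g$recording$data[i, 1]^2), 10,
               tolerance = 1e-9)
  expect_warning(
    m <- inject_outlier_epochs(g$recording,
                               data.frame(onset = c(5, 6), duration = c(2, 2)),
                               gain = 4),
    "merged")
  expect_identical(nrow(m$meta$outlier_epochs), 1L)
  expect_error(inject_outlier_epochs(g$recording,
                                     data.frame(onset = 29, duration = 5), 2),
               "within the recording")
})

test_that("a 10x outlier epoch is caught by the cycle outlier screen", {
  # round trip: inject -> extract HF amplitude -> reject_outlier_cycles
  fs <- 512
  cfg <- synthetic_config(n_channels = 1, duration = 60, coupling_depth = 0,
                          gamma_amp = 0, seed = 71)
  g <- generate_sleep_recording(cfg)
  rec <- inject_outlier_epochs(g$recording,
                               data.frame(onset = 20, duration = 1), gain = 10)
  amp <- inst_amplitude(morlet_bandpass(rec$data[, 1], fs, band_definition(14, 7)))[, 1]
  tt <- (0:(60 * fs - 1)) / fs
  cyc <- segment_cycles(phase = wrap_phase(360 * tt), fs = fs,
                        phase_source = "tacs")
  out <- reject_outlier_cycles(cyc, amp)
  expect_false(out$retained[21])              # the cycle covering 20-21 s
  expect_gte(sum(out$retained), 55)           # and few others
})

test_that("ground truth serializes to JSON", {
  g <- generate_sleep_recording(synthetic_config(n_channels = 1, duration = 20,
                                                 seed = 2))
  path <- tempfile(fileext = ".json")
  write_ground_truth_json(g$ground_truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$seed, 2)
  expect_equal(back$channels$coupling_depth, 0.5)
})
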