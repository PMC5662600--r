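# Harmonic artifact model: fit, subtraction, stimulation phase reference.

fs <- 512
tt <- (0:(fs * 60 - 1)) / fs

test_that("exact model-class input is recovered to numerical precision", {
  x <- 2 * sin(2 * pi * 1 * tt)
  fit <- fit_harmonic_artifact(x, fs, 1)
  expect_equal(fit$b[1], 2, tolerance = 1e-6)
  expect_lt(max(abs(c(fit$a, fit$b[-1], fit$dc))), 1e-6)
  expect_lt(sqrt(fit$residual_ratio), 1e-6)
  expect_identical(length(fit$k), 40L)        # K = floor(40 / f0)
  # full round trip: coefficients regenerate the signal
  expect_lt(max(abs(reconstruct_artifact(fit) - x)), 1e-6)
})

test_that("base frequency refinement finds a 0.1% detuning", {
  x <- sin(2 * pi * 1.001 * tt)
  fit <- fit_harmonic_artifact(x, fs, 1)
  expect_equal(fit$f0, 1.001, tolerance = 1e-4)
  # dense grid-search oracle over f0
  rss <- vapply(seq(0.999, 1.003, by = 5e-5), function(f0) {
    X <- cbind(1, cos(2 * pi * f0 * tt), sin(2 * pi * f0 * tt))
    sum(stats::lm.fit(X, x)$residuals^2)
  }, numeric(1))
  f_grid <- seq(0.999, 1.003, by = 5e-5)[which.min(rss)]
  expect_equal(fit$f0, f_grid, tolerance = 1e-4)
})

test_that("subtraction suppresses a stationary artifact by >= 40 dB", {
  set.seed(2)
  artifact <- 500 * sin(2 * pi * 1 * tt) + 80 * cos(2 * pi * 2 * tt) +
    30 * sin(2 * pi * 3 * tt)
  x <- artifact + rnorm(length(tt), 0, 5)
  fit <- fit_harmonic_artifact(x, fs, 1)
  res <- subtract_artifact(x, fit)
  pgram <- function(v) Mod(stats::fft(v - mean(v)))^2
  for (f in 1:3) {
    bin <- round(f * length(tt) / fs) + 1L
    supp <- 10 * log10(pgram(x)[bin] / pgram(res)[bin])
    expect_gte(supp, 40)
  }
  # identity: subtracting a fit from its own reconstruction leaves zeros
  rec <- reconstruct_artifact(fit)
  expect_lt(max(abs(subtract_artifact(rec, fit))), 1e-9)
})

test_that("subtraction is linear and transparent to the neural signal", {
  set.seed(14)
  artifact <- 400 * sin(2 * pi * 1 * tt)
  y <- 10 * sin(2 * pi * 13 * tt) * (1 + 0.3 * sin(2 * pi * 0.2 * tt))
  fit_x <- fit_harmonic_artifact(artifact, fs, 1)
  lhs <- subtract_artifact(artifact + y, fit_x)
  rhs <- y + (artifact - reconstruct_artifact(fit_x))
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("drifting artifacts degrade the fit and raise the poor-removal flag", {
  set.seed(6)
  cfg <- synthetic_config(n_channels = 1, duration = 60, coupling_depth = 0,
                          gamma_amp = 0, seed = 77)
  g <- generate_sleep_recording(cfg)
  rms <- sd(g$recording$data[, 1])
  drifty <- inject_tacs_artifact(g$recording, 1, sqrt(2) * 10 * rms,
                                 drift = function(t) 1 + 1.2 * sin(2 * pi * t / 40))
  fit <- fit_harmonic_artifact(drifty$data[, 1], fs, 1)
  expect_true(fit$poor_removal)
  stationary <- inject_tacs_artifact(g$recording, 1, sqrt(2) * 10 * rms)
  fit2 <- fit_harmonic_artifact(stationary$data[, 1], fs, 1)
  expect_false(fit2$poor_removal)
})

test_that("stimulation phase follows the 0-degrees-at-anodal-peak convention", {
  x <- 3 * sin(2 * pi * 1 * tt)                # positive peak at t = 0.25
  fit <- fit_harmonic_artifact(x, fs, 1, refine_f0 = FALSE)
  expect_lt(circ_diff(stimulation_phase(fit, 0.25), 0), 0.01)
  expect_lt(circ_diff(stimulation_phase(fit, 0.75), 180), 0.01)
  # periodicity: advancing by exactly 1/f0 leaves the phase unchanged
  expect_lt(circ_diff(stimulation_phase(fit, 0.25 + 1), 0), 0.01)
  # increasing with time just after the peak
  expect_gt(stimulation_phase(fit, 0.26), 0)
  zero <- fit; zero$a[1] <- 0; zero$b[1] <- 0
  expect_error(stimulation_phase(zero, 0), "no phase reference")
})

test_that("stimulation phase agrees with the Morlet phase of the fundamental", {
  x <- 200 * sin(2 * pi * 1 * tt)
  fit <- fit_harmonic_artifact(x, fs, 1, refine_f0 = FALSE)
  ph_fit <- stimulation_phase(fit, tt)
  a <- morlet_bandpass(x, fs, band_definition(1, 1))
  interior <- (a$edge_samples + 1):(length(tt) - a$edge_samples)
  ph_morlet <- inst_phase(a)[interior, 1]
  expect_lt(max(circ_diff(ph_fit[interior], ph_morlet)), 2)
})

test_that("trapezoidal waveforms and short segments are refused", {
  expect_error(fit_harmonic_artifact(rnorm(fs * 60), fs, 1,
                                     waveform = "trapezoidal"),
               "trapezoidal")
  expect_error(fit_harmonic_artifact(rnorm(fs * 5), fs, 1), "10 periods")
})

test_that("harmonic fit serializes to JSON and back", {
  x <- 2 * sin(2 * pi * 1 * tt) + cos(2 * pi * 2 * tt)
  fit <- fit_harmonic_artifact(x, fs, 1, refine_f0 = FALSE)
  path <- tempfile(fileext = ".json")
  write_harmonic_fit_json(fit, path)
  back <- read_harmonic_fit_json(path)
  expect_equal(back$b[1], fit$b[1], tolerance = 1e-12)
  expect_equal(back$f0, fit$f0)
  expect_lt(max(abs(reconstruct_artifact(back, 0:10 / 10) -
                      reconstruct_artifact(fit, 0:10 / 10))), 1e-9)
})
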