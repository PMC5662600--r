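# Synthetic sleep-iEEG generator with known ground truth.
#
# Emulates the features of the real recordings that the analysis depends
# on: unitary broadband slow-oscillation events that stay rhythmic for at
# most two cycles, spindle and gamma bursts whose envelope is
# multiplicatively coupled to the slow-oscillation phase, 1/f background
# noise, a sinusoidal stimulation artifact with harmonic distortion,
# acoustic trigger trains, and movement/outlier epochs. Every draw is
# recorded so downstream stages have a recovery oracle.

#' Configuration for the synthetic sleep-iEEG generator
#'
#' Defaults encode the study conditions the package is validated against:
#' 512 Hz sampling, slow-oscillation events spanning 0.5-4 Hz that remain
#' rhythmic for at most two cycles, ~200 uV peak slow oscillations over a
#' 1/f background, spindle (14/7 Hz) and gamma (90/40 Hz) activity whose
#' envelope is modulated as `1 + depth * cos(phi_SO - preferred_phase)`.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate, Hz.
#' @param duration recording duration, seconds.
#' @param so_event_rate slow-oscillation events per minute.
#' @param so_band frequency range (Hz) events are drawn from (log-uniform).
#' @param max_consecutive_so_cycles rhythmicity limit per event (1 or 2).
#' @param coupling_depth modulation depth in [0, 1], recycled per channel
#'   (applies to both spindle and gamma envelopes).
#' @param preferred_phase preferred coupling phase, degrees, recycled per
#'   channel (0 = slow-oscillation positive peak).
#' @param phase_band [band_definition()] used to define the latent
#'   slow-oscillation phase the coupling references (default (1, 1) Hz).
#' @param spindle_band,gamma_band [band_definition()]s of the coupled
#'   rhythms.
#' @param so_amp peak slow-oscillation amplitude, uV.
#' @param spindle_amp,gamma_amp RMS carrier amplitude, uV (0 disables that
#'   component).
#' @param noise_amp RMS of the 1/f background, uV.
#' @param noise_exponent spectral slope of the background (power ~ f^-a).
#' @param spindle_mode `"continuous"` (ongoing modulated carrier; gives the
#'   closed-form modulation-index oracle depth/2) or `"bursts"` (discrete
#'   Hann-windowed bursts, recorded in the ground truth for detector
#'   round-trips).
#' @param burst_rate bursts per minute (bursts mode).
#' @param seed RNG seed; identical seeds give bit-identical recordings.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_channels = 4, fs = 512, duration = 300,
                             so_event_rate = 30, so_band = c(0.5, 4),
                             max_consecutive_so_cycles = 2,
                             coupling_depth = 0.5, preferred_phase = 0,
                             phase_band = band_definition(1, 1),
                             spindle_band = band_definition(14, 7),
                             gamma_band = band_definition(90, 40),
                             so_amp = 200, spindle_amp = 20, gamma_amp = 5,
                             noise_amp = 15, noise_exponent = 1,
                             spindle_mode = c("continuous", "bursts"),
                             burst_rate = 10, seed = 1L) {
  spindle_mode <- match.arg(spindle_mode)
  check_scalar_num(duration, "duration", lower = 1e-9)
  check_scalar_num(fs, "fs", lower = 1)
  if (length(so_band) != 2L || so_band[1] <= 0 || so_band[2] <= so_band[1])
    stop_field("'so_band' must be c(low, high) with 0 < low < high")
  depth <- rep_len(coupling_depth, n_channels)
  if (any(depth < 0 | depth > 1))
    stop_field("'coupling_depth' must lie in [0, 1]")
  pref <- rep_len(preferred_phase, n_channels)
  for (nm in c("phase_band", "spindle_band", "gamma_band")) {
    b <- as_band(get(nm))
    if (b$fc + b$bw / 2 >= fs / 2)
      stop_field("'%s' (fc = %g, bw = %g) reaches the Nyquist frequency (%g Hz)",
                 nm, b$fc, b$bw, fs / 2)
    assign(nm, b)
  }
  if (so_band[2] >= fs / 2)
    stop_field("'so_band' upper edge %g Hz is at or above Nyquist", so_band[2])
  structure(list(
    n_channels = as.integer(n_channels), fs = fs, duration = duration,
    so_event_rate = so_event_rate, so_band = so_band,
    max_consecutive_so_cycles = as.integer(max_consecutive_so_cycles),
    coupling_depth = depth, preferred_phase = pref,
    phase_band = phase_band, spindle_band = spindle_band,
    gamma_band = gamma_band, so_amp = so_amp, spindle_amp = spindle_amp,
    gamma_amp = gamma_amp, noise_amp = noise_amp,
    noise_exponent = noise_exponent, spindle_mode = spindle_mode,
    burst_rate = burst_rate, seed = as.integer(seed)),
    class = "synthetic_config")
}

# 1/f-shaped Gaussian noise, unit RMS
pink_noise <- function(n, exponent) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                    # avoid DC blow-up
  f <- pmin(f, n - f + 1)                      # symmetric over Nyquist
  shape <- f^(-exponent / 2)
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Hann-windowed unitary slow-oscillation event train for one channel.
so_event_train <- function(cfg, n) {
  rate_s <- cfg$so_event_rate / 60
  x <- numeric(n)
  events <- list()
  t0 <- stats::rexp(1, rate_s)
  while (TRUE) {
    lf <- exp(stats::runif(1, log(cfg$so_band[1]), log(cfg$so_band[2])))
    ncyc <- sample.int(cfg$max_consecutive_so_cycles, 1L)
    dur <- ncyc / lf
    if (t0 + dur >= cfg$duration) break
    i0 <- floor(t0 * cfg$fs) + 1L
    i1 <- min(n, floor((t0 + dur) * cfg$fs))
    tau <- ((i0:i1) - 1) / cfg$fs - t0
    w <- sin(2 * pi * lf * tau) * 0.5 * (1 - cos(2 * pi * tau / dur))
    pk <- max(abs(w))
    amp <- cfg$so_amp * stats::runif(1, 0.85, 1.15)
    if (pk > 0) x[i0:i1] <- x[i0:i1] + w / pk * amp
    events[[length(events) + 1L]] <-
      data.frame(onset = t0, duration = dur, freq = lf, n_cycles = ncyc,
                 amplitude = amp)
    gap <- stats::rexp(1, rate_s)
    t0 <- t0 + dur + gap
  }
  list(signal = x,
       events = if (length(events)) do.call(rbind, events) else
         data.frame(onset = numeric(0), duration = numeric(0),
                    freq = numeric(0), n_cycles = integer(0),
                    amplitude = numeric(0)))
}

# non-overlapping Hann burst envelope; returns envelope + intervals
burst_envelope <- function(cfg, n) {
  rate_s <- cfg$burst_rate / 60
  env <- numeric(n)
  iv <- list()
  t0 <- stats::rexp(1, rate_s)
  while (TRUE) {
    dur <- stats::runif(1, 0.5, 1.5)
    if (t0 + dur >= cfg$duration) break
    i0 <- floor(t0 * cfg$fs) + 1L
    i1 <- min(n, floor((t0 + dur) * cfg$fs))
    tau <- ((i0:i1) - 1) / cfg$fs - t0
    env[i0:i1] <- pmax(env[i0:i1], 0.5 * (1 - cos(2 * pi * tau / dur)))
    iv[[length(iv) + 1L]] <- data.frame(onset = t0, duration = dur)
    t0 <- t0 + dur + stats::rexp(1, rate_s)
  }
  list(env = env,
       intervals = if (length(iv)) do.call(rbind, iv) else
         data.frame(onset = numeric(0), duration = numeric(0)))
}

# modulated narrowband component: carrier filtered from white noise,
# envelope multiplied by (1 + depth * cos(phi_lat - pref))
modulated_band <- function(cfg, band, amp, mod_factor, burst_env = NULL) {
  n <- length(mod_factor)
  carrier <- Re(morlet_bandpass(stats::rnorm(n), cfg$fs, band)$values[, 1L])
  carrier <- carrier / stats::sd(carrier)
  x <- amp * mod_factor * carrier
  if (!is.null(burst_env)) x <- x * burst_env
  x
}

#' Generate a synthetic sleep recording with known coupling structure
#'
#' Builds, per channel: unitary slow-oscillation events (1-2 Hann-windowed
#' cycles at a frequency drawn log-uniformly within `so_band`), spindle and
#' gamma carriers whose envelope is `(1 + depth * cos(phi_SO -
#' preferred_phase))`-modulated against the latent slow-oscillation phase
#' (the Morlet phase of the clean slow-oscillation trace at `phase_band`),
#' and 1/f background noise. All draws are recorded in the returned ground
#' truth.
#'
#' @param config a [synthetic_config()].
#' @param keep_components logical; if TRUE the clean slow-oscillation,
#'   spindle, gamma and noise components and the latent phase are kept in
#'   `recording$meta$components` (memory-heavy; for validation work).
#' @return list with `recording` (a [ts_recording()]) and `ground_truth`
#'   (class `synthetic_ground_truth`): per-channel injected coupling depth
#'   and preferred phase, slow-oscillation event tables, burst intervals
#'   (bursts mode), and the seed.
#' @export
generate_sleep_recording <- function(config, keep_components = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- round(config$duration * config$fs)
  data <- matrix(0, n, config$n_channels)
  per_channel <- vector("list", config$n_channels)
  components <- if (keep_components) vector("list", config$n_channels) else NULL

  for (ch in seq_len(config$n_channels)) {
    chs <- with_seed(derive_seed(config$seed, ch), {
      so <- so_event_train(config, n)
      lat <- morlet_bandpass(so$signal, config$fs, config$phase_band)
      phi_lat <- Arg(lat$values[, 1L])
      mod <- 1 + config$coupling_depth[ch] *
        cos(phi_lat - deg2rad(config$preferred_phase[ch]))
      bursts <- if (config$spindle_mode == "bursts") burst_envelope(config, n)
      sp <- if (config$spindle_amp > 0)
        modulated_band(config, config$spindle_band, config$spindle_amp, mod,
                       bursts$env) else numeric(n)
      gm <- if (config$gamma_amp > 0)
        modulated_band(config, config$gamma_band, config$gamma_amp, mod)
        else numeric(n)
      nz <- if (config$noise_amp > 0)
        config$noise_amp * pink_noise(n, config$noise_exponent) else numeric(n)
      list(signal = so$signal + sp + gm + nz,
           so_events = so$events,
           burst_intervals = if (!is.null(bursts)) bursts$intervals,
           comp = if (keep_components)
             list(so = so$signal, spindle = sp, gamma = gm, noise = nz,
                  latent_phase_deg = wrap_phase(rad2deg(phi_lat))))
    })
    data[, ch] <- chs$signal
    per_channel[[ch]] <- list(
      coupling_depth = config$coupling_depth[ch],
      preferred_phase = config$preferred_phase[ch],
      so_events = chs$so_events,
      burst_intervals = chs$burst_intervals)
    if (keep_components) components[[ch]] <- chs$comp
  }

  rec <- ts_recording(data, fs = config$fs,
                      meta = list(synthetic = TRUE, seed = config$seed))
  if (keep_components) rec$meta$components <- components
  gt <- structure(list(seed = config$seed, config = config,
                       channels = per_channel,
                       artifact = NULL, triggers = NULL,
                       outlier_epochs = NULL),
                  class = "synthetic_ground_truth")
  list(recording = rec, ground_truth = gt)
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat(sprintf("<synthetic_ground_truth> %d channels, seed %d\n",
              length(x$channels), x$seed))
  d <- vapply(x$channels, `[[`, numeric(1), "coupling_depth")
  cat("  coupling depths:", paste(signif(d, 3), collapse = " "), "\n")
  invisible(x)
}

#' Inject a sinusoidal stimulation artifact with harmonic distortion
#'
#' Adds `amplitude * sin(2 pi f_stim t)` plus optional harmonic terms to
#' every channel (scaled per channel by `channel_scale`, since the
#' artifact amplitude varies with electrode distance), optionally with a
#' slow multiplicative amplitude drift. In typical use the artifact
#' exceeds the neural signal more than ten-fold.
#'
#' @param rec a [ts_recording()].
#' @param f_stim stimulation frequency, Hz (0.75 or 1 typical).
#' @param amplitude fundamental amplitude, uV (> 0).
#' @param harmonic_coeffs optional data.frame with columns `k` (harmonic
#'   number >= 2), `a` (cosine) and `b` (sine) coefficients, uV.
#' @param drift optional amplitude drift: a function of time (seconds)
#'   returning a multiplicative envelope, or a scalar fractional slope per
#'   second.
#' @param channel_scale per-channel scale factors (recycled).
#' @param ground_truth optional `synthetic_ground_truth` to update.
#' @return the modified recording (artifact parameters recorded in
#'   `meta$artifact`); if `ground_truth` is supplied, a list
#'   `(recording, ground_truth)`.
#' @export
inject_tacs_artifact <- function(rec, f_stim, amplitude,
                                 harmonic_coeffs = NULL, drift = NULL,
                                 channel_scale = 1, ground_truth = NULL) {
  stopifnot(inherits(rec, "ts_recording"))
  check_scalar_num(amplitude, "amplitude", lower = .Machine$double.eps)
  check_scalar_num(f_stim, "f_stim", lower = 1e-9)
  if (f_stim >= rec$fs / 2)
    stop_field("f_stim = %g Hz is at or above Nyquist (%g Hz)", f_stim, rec$fs / 2)
  n <- nrow(rec$data)
  tt <- (seq_len(n) - 1) / rec$fs
  wave <- amplitude * sin(2 * pi * f_stim * tt)
  if (!is.null(harmonic_coeffs)) {
    if (!all(c("k", "a", "b") %in% names(harmonic_coeffs)))
      stop_field("'harmonic_coeffs' needs columns k, a, b")
    if (any(harmonic_coeffs$k * f_stim >= rec$fs / 2))
      stop_field("harmonic frequency %g Hz is at or above Nyquist (%g Hz)",
                 max(harmonic_coeffs$k) * f_stim, rec$fs / 2)
    for (i in seq_len(nrow(harmonic_coeffs))) {
      w <- 2 * pi * harmonic_coeffs$k[i] * f_stim * tt
      wave <- wave + harmonic_coeffs$a[i] * cos(w) + harmonic_coeffs$b[i] * sin(w)
    }
  }
  env <- if (is.null(drift)) 1
  else if (is.function(drift)) drift(tt)
  else 1 + drift * (tt - mean(tt))
  wave <- wave * env
  scl <- rep_len(channel_scale, ncol(rec$data))
  rec$data <- rec$data + outer(wave, scl)
  rec$meta$artifact <- list(f_stim = f_stim, amplitude = amplitude,
                            harmonic_coeffs = harmonic_coeffs,
                            drift = !is.null(drift),
                            channel_scale = scl)
  if (!is.null(ground_truth)) {
    ground_truth$artifact <- rec$meta$artifact
    return(list(recording = rec, ground_truth = ground_truth))
  }
  rec
}

#' Generate an acoustic trigger train
#'
#' Trigger onset times for 50-ms pink-noise burst stimulation repeated at
#' `rate` Hz; with `jitter = 0` the inter-trigger interval is exactly
#' `1 / rate` (300 triggers in a 5-min block at 1 Hz, 225 at 0.75 Hz).
#'
#' @param rate trigger rate, Hz (> 0).
#' @param duration block duration, seconds.
#' @param jitter SD of Gaussian onset jitter, seconds (default 0).
#' @param seed RNG seed (used only when `jitter > 0`).
#' @return numeric vector of trigger times in `[0, duration)`, seconds.
#' @export
generate_acoustic_triggers <- function(rate, duration, jitter = 0, seed = NULL) {
  check_scalar_num(rate, "rate", lower = 1e-9)
  check_scalar_num(duration, "duration", lower = 0)
  base <- seq(0, by = 1 / rate, length.out = max(0L, floor(duration * rate)))
  if (length(base) && duration - base[length(base)] < 1e-12 * max(1, duration))
    base <- base[-length(base)]
  if (jitter > 0 && length(base)) {
    base <- with_seed(seed, base + stats::rnorm(length(base), 0, jitter))
    base <- sort(pmin(pmax(base, 0), duration - 1e-9))
  }
  base
}

#' Inject broadband outlier epochs (movement-like artifacts)
#'
#' Multiplies broadband power by `gain` inside the given intervals
#' (amplitude by `sqrt(gain)`); overlapping intervals are merged with a
#' warning. `gain = 1` leaves the recording unchanged.
#'
#' @param rec a [ts_recording()].
#' @param intervals data.frame with `onset` and `duration` (seconds), or a
#'   2-column matrix of (onset, duration).
#' @param gain broadband power gain inside the epochs (> 0).
#' @param ground_truth optional `synthetic_ground_truth` to update.
#' @return the modified recording (epochs recorded in
#'   `meta$outlier_epochs`); with `ground_truth`, a list
#'   `(recording, ground_truth)`.
#' @export
inject_outlier_epochs <- function(rec, intervals, gain, ground_truth = NULL) {
  stopifnot(inherits(rec, "ts_recording"))
  check_scalar_num(gain, "gain", lower = .Machine$double.eps)
  if (is.matrix(intervals))
    intervals <- data.frame(onset = intervals[, 1L], duration = intervals[, 2L])
  if (!all(c("onset", "duration") %in% names(intervals)))
    stop_field("'intervals' needs onset and duration columns")
  dur_total <- rec_duration(rec)
  if (any(intervals$onset < 0 | intervals$onset + intervals$duration > dur_total))
    stop_field("outlier intervals must lie within the recording [0, %g] s", dur_total)
  o <- order(intervals$onset)
  iv <- intervals[o, , drop = FALSE]
  merged <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- nrow(merged)
    if (iv$onset[i] < merged$onset[last] + merged$duration[last]) {
      warning("overlapping outlier intervals merged", call. = FALSE)
      merged$duration[last] <- max(merged$onset[last] + merged$duration[last],
                                   iv$onset[i] + iv$duration[i]) - merged$onset[last]
    } else merged <- rbind(merged, iv[i, , drop = FALSE])
  }
  g <- sqrt(gain)
  for (i in seq_len(nrow(merged))) {
    i0 <- floor(merged$onset[i] * rec$fs) + 1L
    i1 <- min(nrow(rec$data), ceiling((merged$onset[i] + merged$duration[i]) * rec$fs))
    rec$data[i0:i1, ] <- rec$data[i0:i1, ] * g
  }
  rec$meta$outlier_epochs <- cbind(merged, gain = gain)
  if (!is.null(ground_truth)) {
    ground_truth$outlier_epochs <- rec$meta$outlier_epochs
    return(list(recording = rec, ground_truth = ground_truth))
  }
  rec
}

#' Serialize synthetic ground truth to JSON
#' @param gt a `synthetic_ground_truth`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_ground_truth_json <- function(gt, path) {
  x <- unclass(gt)
  x$config <- lapply(unclass(x$config), function(v)
    if (inherits(v, "band_definition")) unclass(v) else v)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
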