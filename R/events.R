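# Sleep spindle and slow-wave event detection, event phase preference, and
# stimulus-locked event-rate comparison.

# Broadband (default 1-45 Hz) instantaneous power with the detection band
# excised entirely (brick-wall spectral mask over [edges] minus
# [fc - bw, fc + bw]), so a duration-respecting spindle cannot trip its
# own artifact screen, while movement artifacts and sub-duration
# transients — which are spectrally wide by the uncertainty principle —
# do. Returns the envelope-squared power and the reference distribution
# of sliding-window maxima.
broadband_screen <- function(signal, fs, band, edges = c(1, 45), win_s = 1) {
  n <- length(signal)
  X <- stats::fft(signal - mean(signal))
  f <- (seq_len(n) - 1) * fs / n
  fpos <- pmin(f, fs - f)
  keep <- fpos >= edges[1L] & fpos <= edges[2L] &
    !(fpos > band$fc - band$bw & fpos < band$fc + band$bw)
  X[!keep] <- 0
  neg <- f > fs / 2                            # analytic signal: envelope
  X[neg] <- 0
  X[!neg & f > 0] <- 2 * X[!neg & f > 0]
  pw <- Mod(stats::fft(X, inverse = TRUE) / n)^2
  w <- max(2L, round(win_s * fs))
  nw <- floor(length(pw) / w)
  wmax <- vapply(seq_len(nw), function(i) max(pw[((i - 1L) * w + 1L):(i * w)]),
                 numeric(1))
  list(power = pw, window_max = wmax)
}

#' Detect sleep spindles by median-referenced power thresholding
#'
#' Instantaneous power in the spindle band (squared Morlet amplitude) is
#' compared against an upper threshold of six times its median; for each
#' crossing, onset and offset are extended outward to where the power falls
#' below a lower threshold (mean + 1 SD of the power). Events lasting
#' 0.2-2 s are kept. Events coinciding with broadband power increases
#' (movement artifacts) are excluded: an event is dropped when its maximum
#' broadband power (1-45 Hz with the spindle band excised, so only
#' sideband energy counts) exceeds the `broadband_quantile` of the
#' distribution of 1-s window maxima over the whole recording
#' (`invert_broadband_screen` flips the rule for sensitivity analyses).
#'
#' @param signal numeric vector, one channel.
#' @param fs sampling rate, Hz.
#' @param band spindle [band_definition()] (default fast spindle (14, 7)).
#' @param upper_mult upper threshold in multiples of the median power.
#' @param duration_range keep events with duration in this range, seconds.
#' @param broadband_edges broadband screen band, Hz.
#' @param broadband_quantile exclusion quantile of window maxima.
#' @param invert_broadband_screen logical; invert the exclusion rule.
#' @return data.frame of `spindle_event`s: `onset`, `offset`, `duration`
#'   (s), `peak_time` (time of maximum band power, s), `peak_power`
#'   (uV^2), `excluded_broadband` (logical; excluded events are returned
#'   flagged, not silently dropped... only rows with
#'   `excluded_broadband = FALSE` count as detections).
#' @export
detect_spindles <- function(signal, fs, band = band_definition(14, 7),
                            upper_mult = 6, duration_range = c(0.2, 2),
                            broadband_edges = c(1, 45),
                            broadband_quantile = 0.9,
                            invert_broadband_screen = FALSE) {
  if (length(signal) < 60 * fs)
    stop_field("need >= 60 s of signal for stable spindle thresholds (got %.1f s)",
               length(signal) / fs)
  band <- as_band(band)
  flt <- morlet_bandpass(signal, fs, band)
  pw <- Mod(flt$values[, 1L])^2
  edge <- flt$edge_samples
  upper <- upper_mult * stats::median(pw)
  lower <- min(mean(pw) + stats::sd(pw), upper)

  above <- pw > upper
  if (!any(above)) return(empty_spindles())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])

  # extend each crossing to the lower threshold, then merge overlaps
  low <- pw > lower
  ev <- t(apply(seg, 1L, function(s) {
    a <- s[1L]; b <- s[2L]
    while (a > 1L && low[a - 1L]) a <- a - 1L
    while (b < length(pw) && low[b + 1L]) b <- b + 1L
    c(a, b)
  }))
  ev <- ev[!duplicated(ev[, 1L]), , drop = FALSE]

  scr <- broadband_screen(signal, fs, band, broadband_edges)
  bb_thr <- stats::quantile(scr$window_max, broadband_quantile, names = FALSE)

  out <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    a <- ev[i, 1L]; b <- ev[i, 2L]
    if (a <= edge || b > length(pw) - edge) return(NULL)   # filter edge region
    dur <- (b - a + 1L) / fs
    if (dur < duration_range[1L] || dur > duration_range[2L]) return(NULL)
    pk <- a + which.max(pw[a:b]) - 1L
    bb_max <- max(scr$power[a:b])
    excl <- bb_max > bb_thr
    if (invert_broadband_screen) excl <- !excl
    data.frame(onset = (a - 1L) / fs, offset = b / fs, duration = dur,
               peak_time = (pk - 1L) / fs, peak_power = pw[pk],
               excluded_broadband = excl)
  }))
  if (is.null(out)) return(empty_spindles())
  class(out) <- c("spindle_events", "data.frame")
  out
}

empty_spindles <- function() {
  structure(data.frame(onset = numeric(0), offset = numeric(0),
                       duration = numeric(0), peak_time = numeric(0),
                       peak_power = numeric(0),
                       excluded_broadband = logical(0)),
            class = c("spindle_events", "data.frame"))
}

#' Detect slow waves by paired negative zero-crossings
#'
#' The signal is bandpass filtered at the slow-oscillation band
#' (fc = 0.75 Hz, bandwidth = 0.75 Hz by default); negative-going zero
#' crossings of the filtered trace are paired when separated by 0.5-2 s,
#' and the down-state is the minimum voltage within the pair.
#'
#' @param signal numeric vector, one channel.
#' @param fs sampling rate, Hz.
#' @param band slow-oscillation [band_definition()].
#' @param crossing_range allowed separation of the two negative
#'   zero-crossings, seconds.
#' @param min_down_uV optional amplitude criterion: drop events whose
#'   down-state is shallower than this (uV). The bare zero-crossing
#'   algorithm accepts arbitrarily small slow-band fluctuations, so an
#'   amplitude floor is useful whenever background activity is present;
#'   `NULL` (default) keeps the literal crossing rule.
#' @return data.frame of `slow_wave_event`s: `neg_zc1`, `neg_zc2` (s),
#'   `duration`, `down_time`, `down_voltage` (filtered-trace minimum, uV).
#' @export
detect_slow_waves <- function(signal, fs, band = band_definition(0.75, 0.75),
                              crossing_range = c(0.5, 2), min_down_uV = NULL) {
  if (length(signal) < 30 * fs)
    stop_field("need >= 30 s of signal for slow-wave detection (got %.1f s)",
               length(signal) / fs)
  flt <- morlet_bandpass(signal, fs, as_band(band))
  x <- Re(flt$values[, 1L])
  # events inside the filter's edge-transient region are unreliable
  lo <- flt$edge_samples + 1L
  hi <- length(x) - flt$edge_samples
  neg <- which(x[-length(x)] > 0 & x[-1L] <= 0)      # positive -> negative
  neg <- neg[neg >= lo & neg <= hi]
  if (length(neg) < 2L) return(empty_slow_waves())
  out <- do.call(rbind, lapply(seq_len(length(neg) - 1L), function(i) {
    sep <- (neg[i + 1L] - neg[i]) / fs
    if (sep < crossing_range[1L] || sep > crossing_range[2L]) return(NULL)
    idx <- neg[i]:neg[i + 1L]
    j <- idx[which.min(x[idx])]
    data.frame(neg_zc1 = (neg[i] - 1L) / fs, neg_zc2 = (neg[i + 1L] - 1L) / fs,
               duration = sep, down_time = (j - 1L) / fs, down_voltage = x[j])
  }))
  if (is.null(out)) return(empty_slow_waves())
  if (!is.null(min_down_uV))
    out <- out[out$down_voltage <= -min_down_uV, , drop = FALSE]
  class(out) <- c("slow_wave_events", "data.frame")
  out
}

empty_slow_waves <- function() {
  structure(data.frame(neg_zc1 = numeric(0), neg_zc2 = numeric(0),
                       duration = numeric(0), down_time = numeric(0),
                       down_voltage = numeric(0)),
            class = c("slow_wave_events", "data.frame"))
}

#' Preferred slow-oscillation phase of detected events
#'
#' Samples the low-frequency phase at each event's peak time and reports
#' the circular mean and a Rayleigh non-uniformity test.
#'
#' @param event_times event peak times, seconds (e.g. `peak_time` of
#'   detected spindles).
#' @param phase numeric vector of instantaneous phase per sample, degrees.
#' @param fs sampling rate, Hz.
#' @return list with `preferred_phase` (degrees), `rbar`, `p` (Rayleigh),
#'   `n`.
#' @export
event_phase_preference <- function(event_times, phase, fs) {
  if (length(event_times) < 5L)
    stop_field("need >= 5 events for a phase preference (got %d)",
               length(event_times))
  idx <- pmin(pmax(round(event_times * fs) + 1L, 1L), length(phase))
  rt <- rayleigh_test(phase[idx])
  list(preferred_phase = rt$mean_phase, rbar = rt$rbar, p = rt$p, n = rt$n)
}

#' Chi-square comparison of stimulus-locked event counts against baseline
#'
#' Compares a stimulus-locked event-count histogram against the
#' expectation derived from baseline counts (scaled to the same total),
#' with `dof = bins - 1`.
#'
#' @param stim_counts integer vector of event counts per time bin during
#'   stimulation.
#' @param baseline_counts integer vector, same binning, baseline condition.
#' @return list with `chisq`, `dof`, `p`, `expected`.
#' @export
event_rate_comparison <- function(stim_counts, baseline_counts) {
  if (length(stim_counts) == 0L || length(baseline_counts) == 0L)
    stop_field("empty count table")
  if (length(stim_counts) != length(baseline_counts))
    stop_field("count vectors must share the same binning (%d vs %d bins)",
               length(stim_counts), length(baseline_counts))
  if (sum(baseline_counts) == 0) stop_field("baseline counts are all zero")
  expected <- baseline_counts * sum(stim_counts) / sum(baseline_counts)
  if (mean(expected < 5) > 0.2)
    warning("expected counts < 5 in more than 20% of bins; chi-square approximation is weak",
            call. = FALSE)
  keep <- expected > 0
  chisq <- sum((stim_counts[keep] - expected[keep])^2 / expected[keep])
  dof <- length(stim_counts) - 1L
  list(chisq = chisq, dof = dof,
       p = stats::pchisq(chisq, dof, lower.tail = FALSE), expected = expected)
}

#' Write detected events as a BIDS-style events table
#' @param events a `spindle_events` or `slow_wave_events` data.frame.
#' @param path output TSV path.
#' @param channel channel label to record.
#' @return `path` invisibly.
#' @export
write_detected_events_tsv <- function(events, path, channel = "ch1") {
  if (inherits(events, "spindle_events")) {
    df <- data.frame(onset = events$onset, duration = events$duration,
                     label = "spindle", channel = channel,
                     peak_metric = events$peak_power)
  } else if (inherits(events, "slow_wave_events")) {
    df <- data.frame(onset = events$neg_zc1, duration = events$duration,
                     label = "slow_wave", channel = channel,
                     peak_metric = events$down_voltage)
  } else stop_field("unsupported events object")
  write_events_tsv(df, path)
}
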