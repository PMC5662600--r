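# Spindle-gamma amplitude cross-correlation, pre/post stimulation band
# power change, and post-stimulation phase coherence.

# FFT brick-wall lowpass (zero-phase); used to smooth amplitude envelopes
# so carrier leakage does not dominate the cross-correlation
fft_lowpass <- function(x, fs, cutoff) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X[f > cutoff] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Cross-correlation of two instantaneous-amplitude envelopes
#'
#' Pearson correlation at each lag between two amplitude envelopes
#' (low-pass smoothed at `smooth_hz` to suppress carrier leakage).
#' Convention: a positive peak lag means the first series precedes the
#' second.
#'
#' @param amp_a,amp_b equal-length numeric envelopes.
#' @param fs sampling rate, Hz.
#' @param max_lag maximum lag, seconds.
#' @param smooth_hz low-pass cutoff for envelope smoothing (`NULL` to
#'   disable).
#' @return list with `lags` (s), `correlation`, `peak_lag` (s),
#'   `peak_value`.
#' @export
amplitude_crosscorrelation <- function(amp_a, amp_b, fs, max_lag = 1,
                                       smooth_hz = 5) {
  if (length(amp_a) != length(amp_b))
    stop_field("envelopes must have equal length (%d vs %d)",
               length(amp_a), length(amp_b))
  L <- round(max_lag * fs)
  if (length(amp_a) < 10L * L)
    stop_field("series too short: need >= 10 * max_lag (%d samples), got %d",
               10L * L, length(amp_a))
  if (!is.null(smooth_hz)) {
    amp_a <- fft_lowpass(amp_a, fs, smooth_hz)
    amp_b <- fft_lowpass(amp_b, fs, smooth_hz)
  }
  if (stats::sd(amp_a) == 0 || stats::sd(amp_b) == 0)
    stop_field("constant envelope: correlation undefined")
  n <- length(amp_a)
  lags <- (-L):L
  cc <- vapply(lags, function(l) {
    # positive l: amp_a precedes amp_b by l samples
    if (l >= 0) stats::cor(amp_a[1:(n - l)], amp_b[(1 + l):n])
    else stats::cor(amp_a[(1 - l):n], amp_b[1:(n + l)])
  }, numeric(1))
  k <- which.max(cc)
  list(lags = lags / fs, correlation = cc, peak_lag = lags[k] / fs,
       peak_value = cc[k])
}

#' Band power change after stimulation blocks
#'
#' Multitaper band power of 30-s segments immediately after each
#' stimulation block compared against the 30 s preceding the first block.
#'
#' Significance per band and segment treats each band-integrated power as
#' a scaled chi-square with `2 * bw * T` degrees of freedom (the number of
#' independent spectral components a segment of duration T contributes to
#' a band of width bw), giving an F-test on the power ratio. A jackknife
#' across tapers is *not* used here: per-taper band powers share the
#' realized noise energy in the band, so their scatter grossly
#' underestimates the between-segment variance.
#'
#' @param pre numeric vector, the pre-stimulation segment (exactly
#'   `segment_s` seconds, tolerance one sample).
#' @param post list of numeric vectors (or one vector), post-block
#'   segments of the same length.
#' @param fs sampling rate, Hz.
#' @param bands named list of [band_definition()]s.
#' @param segment_s required segment duration, seconds (default 30).
#' @param k number of sine tapers.
#' @return data.frame with one row per band x post segment: `band`,
#'   `segment`, `power_pre`, `power_post`, `log2_ratio`, `ci_lo`, `ci_hi`
#'   (log2 ratio 95% CI), `p` (two-sided F-test), `dof` (per segment).
#' @export
band_power_change <- function(pre, post, fs, bands, segment_s = 30, k = 5L) {
  if (!is.list(post)) post <- list(post)
  need <- round(segment_s * fs)
  for (seg in c(list(pre), post))
    if (abs(length(seg) - need) > 1L)
      stop_field("segments must be exactly %g s (%d samples); got %d",
                 segment_s, need, length(seg))
  if (is.null(names(bands))) names(bands) <- paste0("band", seq_along(bands))
  out <- list()
  for (bn in names(bands)) {
    band <- as_band(bands[[bn]])
    m <- max(2L, round(band$bw * segment_s))   # independent components
    mp_pre <- multitaper_power(pre, fs, band, k = k)
    for (si in seq_along(post)) {
      mp_post <- multitaper_power(post[[si]], fs, band, k = k)
      fstat <- mp_post$power / mp_pre$power
      p <- 2 * min(stats::pf(fstat, 2 * m, 2 * m),
                   stats::pf(fstat, 2 * m, 2 * m, lower.tail = FALSE))
      qs <- stats::qf(c(0.975, 0.025), 2 * m, 2 * m)
      out[[length(out) + 1L]] <- data.frame(
        band = bn, segment = si,
        power_pre = mp_pre$power, power_post = mp_post$power,
        log2_ratio = log2(fstat),
        ci_lo = log2(fstat / qs[1L]), ci_hi = log2(fstat / qs[2L]),
        p = min(p, 1), dof = 2 * m)
    }
  }
  do.call(rbind, out)
}

#' Post-stimulation phase coherence across trials
#'
#' Each stimulation-free window immediately after a block is fit with a
#' sinusoid (frequency searched over `f_range`, default 0.5-1.5 Hz in
#' 0.01-Hz steps; amplitude and phase solved linearly at each frequency),
#' and the inter-trial coherence is the resultant length of the fitted
#' phases evaluated at the window start (the stimulation offset).
#' Significance via the Rayleigh test.
#'
#' @param trials list of numeric vectors (or matrix trials x samples),
#'   one post-stimulation window per trial.
#' @param fs sampling rate, Hz.
#' @param f_range frequency search range, Hz.
#' @param f_step frequency grid step, Hz.
#' @return list with `phases` (per-trial fitted phase at window start,
#'   degrees), `frequencies`, `amplitudes`, `coherence` (resultant
#'   length), `mean_phase` (degrees), `p` (Rayleigh),
#'   `edge_fraction` (trials whose fitted frequency pinned at a range
#'   edge; a warning is raised above 0.5).
#' @export
post_stim_phase_coherence <- function(trials, fs, f_range = c(0.5, 1.5),
                                      f_step = 0.01) {
  if (is.matrix(trials)) trials <- asplit(trials, 1L)
  if (length(trials) < 10L)
    stop_field("need >= 10 trials (got %d)", length(trials))
  fgrid <- seq(f_range[1L], f_range[2L], by = f_step)
  fit_one <- function(x) {
    n <- length(x)
    tt <- (seq_len(n) - 1) / fs
    x <- x - mean(x)
    best <- NULL
    for (f in fgrid) {
      C <- cos(2 * pi * f * tt); S <- sin(2 * pi * f * tt)
      cf <- stats::lm.fit(cbind(C, S), x)$coefficients
      rss <- sum((x - cbind(C, S) %*% cf)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(rss = rss, f = f, a = cf[1L], b = cf[2L])
    }
    # a*cos + b*sin = A*cos(2 pi f t - phi0); phase at t = 0 is -phi0... the
    # fitted phase AT the window start is the argument of the cosine there
    list(f = best$f, amp = sqrt(best$a^2 + best$b^2),
         phase = wrap_phase(rad2deg(-atan2(best$b, best$a))))
  }
  fits <- lapply(trials, fit_one)
  freqs <- vapply(fits, `[[`, numeric(1), "f")
  phases <- vapply(fits, `[[`, numeric(1), "phase")
  amps <- vapply(fits, `[[`, numeric(1), "amp")
  edge <- mean(abs(freqs - f_range[1L]) < f_step / 2 |
                 abs(freqs - f_range[2L]) < f_step / 2)
  if (edge > 0.5)
    warning(sprintf("fitted frequency pinned at the range edge in %.0f%% of trials",
                    100 * edge), call. = FALSE)
  rt <- rayleigh_test(phases)
  list(phases = phases, frequencies = freqs, amplitudes = amps,
       coherence = rt$rbar, mean_phase = rt$mean_phase, p = rt$p,
       edge_fraction = edge)
}
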