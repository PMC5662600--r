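# Band decomposition into instantaneous amplitude/phase, multitaper power,
# and time-frequency responses.

#' Define a frequency band by center frequency and bandwidth
#'
#' Bands are specified the way the analysis parameterizes its wavelets: a
#' center frequency `fc` and a bandwidth `bw`, where `bw` is the full width
#' at half maximum of the wavelet's frequency-domain magnitude response.
#' Canonical bands for sleep iEEG work: fast spindle (14, 7), slow spindle /
#' alpha (10, 5), theta (7, 3.5), gamma (90, 40), slow oscillation (1, 1)
#' or (0.75, 0.75).
#'
#' @param fc center frequency, Hz.
#' @param bw bandwidth (FWHM of the magnitude response), Hz.
#' @return an object of class `band_definition`.
#' @examples
#' fast_spindle <- band_definition(14, 7)   # half-power 10.5 - 17.5 Hz
#' @export
band_definition <- function(fc, bw) {
  check_scalar_num(fc, "fc", lower = .Machine$double.eps)
  check_scalar_num(bw, "bw", lower = .Machine$double.eps)
  if (bw > 2 * fc)
    stop_field("'bw' (%g) must not exceed 2*fc (%g): band would reach below 0 Hz",
               bw, 2 * fc)
  structure(list(fc = fc, bw = bw), class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> fc = %g Hz, bw (FWHM) = %g Hz [%g - %g Hz half-power]\n",
              x$fc, x$bw, x$fc - x$bw / 2, x$fc + x$bw / 2))
  invisible(x)
}

as_band <- function(band) {
  if (inherits(band, "band_definition")) return(band)
  if (is.numeric(band) && length(band) == 2L) return(band_definition(band[1L], band[2L]))
  stop_field("'band' must be a band_definition or c(fc, bw)")
}

# Gaussian width in the frequency domain from the FWHM bandwidth.
band_sigma_f <- function(band) band$bw / (2 * sqrt(2 * log(2)))

# One-sided wavelet support in samples (4 temporal sigmas).
morlet_support <- function(band, fs) {
  sigma_t <- 1 / (2 * pi * band_sigma_f(band))
  ceiling(4 * sigma_t * fs)
}

#' Complex Morlet bandpass: instantaneous amplitude and phase
#'
#' Convolves each channel with a complex Morlet wavelet centered at
#' `band$fc` whose frequency-domain magnitude response has full width at
#' half maximum `band$bw`. The modulus of the output is the instantaneous
#' amplitude in input units (a unit-amplitude sinusoid at `fc` maps to
#' amplitude 1); the argument is the instantaneous phase, with 0 degrees at
#' the positive peaks of an in-band cosine — the phase convention every
#' other module inherits.
#'
#' Edges are handled by reflect-padding with one wavelet support length and
#' discarding the pads; the `edge_samples` field reports how many samples at
#' each end are still influenced by the boundary so downstream cycle
#' segmentation can flag them rather than silently keep them.
#'
#' @param x a `ts_recording`, or numeric vector/matrix (samples x channels).
#' @param fs sampling rate, Hz (ignored when `x` is a recording).
#' @param band a [band_definition()] or `c(fc, bw)`.
#' @return an object of class `analytic_signal`: list with complex matrix
#'   `values` (samples x channels), `fs`, `band`, `edge_samples`.
#' @examples
#' fs <- 256; t <- seq(0, 4, by = 1 / fs)
#' a <- morlet_bandpass(cos(2 * pi * 14 * t), fs, band_definition(14, 7))
#' range(Mod(a$values[500:600, 1]))   # ~1
#' @export
morlet_bandpass <- function(x, fs = NULL, band) {
  s <- as_signal_matrix(x, fs)
  band <- as_band(band)
  nyq <- s$fs / 2
  if (band$fc + band$bw / 2 >= nyq)
    stop_field("band (fc = %g, bw = %g) reaches %g Hz, at or above Nyquist (%g Hz)",
               band$fc, band$bw, band$fc + band$bw / 2, nyq)
  n <- nrow(s$data)
  sup <- morlet_support(band, s$fs)
  if (n < 3L * (2L * sup + 1L))
    stop_field("signal too short: %d samples < 3 wavelet supports (%d samples)",
               n, 3L * (2L * sup + 1L))

  sigma_t <- 1 / (2 * pi * band_sigma_f(band))
  tk <- seq.int(-sup, sup) / s$fs
  g <- exp(-tk^2 / (2 * sigma_t^2))
  w <- exp(1i * 2 * pi * band$fc * tk) * g
  # zero-mean correction: a DC offset must not leak into the amplitude
  w <- w - g * (sum(w) / sum(g))
  # scale so a unit cosine at fc has output modulus 1
  w <- w * (2 / sum(Re(w * exp(-1i * 2 * pi * band$fc * tk))))

  # reflect-pad by one support, FFT convolution, discard pads
  nfft <- stats::nextn(n + 2L * sup + length(w) - 1L, 2)
  wf <- stats::fft(c(w, complex(real = numeric(nfft - length(w)))))
  out <- matrix(complex(real = 0), n, ncol(s$data))
  for (ch in seq_len(ncol(s$data))) {
    xi <- s$data[, ch]
    xp <- c(xi[(sup + 1L):2L], xi, xi[(n - 1L):(n - sup)])
    xf <- stats::fft(c(xp, numeric(nfft - length(xp))))
    y <- stats::fft(xf * wf, inverse = TRUE) / nfft
    # kernel is centered at index sup+1 of w; valid alignment offset:
    out[, ch] <- y[(2L * sup + 1L):(2L * sup + n)]
  }
  colnames(out) <- colnames(s$data)
  structure(list(values = out, fs = s$fs, band = band, edge_samples = sup),
            class = "analytic_signal")
}

#' @export
print.analytic_signal <- function(x, ...) {
  cat(sprintf("<analytic_signal> %d x %d @ %g Hz, band fc = %g bw = %g, %d edge samples\n",
              nrow(x$values), ncol(x$values), x$fs, x$band$fc, x$band$bw,
              x$edge_samples))
  invisible(x)
}

#' Instantaneous amplitude / phase of an analytic signal
#' @param a an `analytic_signal`.
#' @return numeric matrix: amplitude in input units, or phase in degrees
#'   wrapped to (-180, 180].
#' @export
inst_amplitude <- function(a) Mod(a$values)

#' @rdname inst_amplitude
#' @export
inst_phase <- function(a) wrap_phase(rad2deg(Arg(a$values)))

# ---------------------------------------------------------------------------

#' Multitaper band power with jackknife confidence interval
#'
#' Band-integrated power spectral density using `k` sine tapers
#' (Riedel-Sidorenko). The estimate satisfies Parseval: integrated over all
#' frequencies it recovers the segment variance. The confidence interval is
#' a leave-one-taper-out jackknife on log power.
#'
#' @param segment numeric vector, a single-channel segment.
#' @param fs sampling rate, Hz.
#' @param band [band_definition()] or `c(fc, bw)`; band edges are
#'   `fc - bw/2` to `fc + bw/2`. `NULL` integrates over the whole spectrum.
#' @param k number of sine tapers (default 5).
#' @param conf confidence level for the jackknife interval.
#' @return list with `power` (variance units, e.g. uV^2), `ci` (length-2),
#'   `df_jackknife`, `k`, and the per-taper estimates.
#' @export
multitaper_power <- function(segment, fs, band = NULL, k = 5L, conf = 0.95) {
  if (!is.numeric(segment) || length(segment) < 8L)
    stop_field("'segment' must be a numeric vector of at least 8 samples")
  if (!is.null(band)) {
    band <- as_band(band)
    f_lo <- max(band$fc - band$bw / 2, 0)
    need <- ceiling(10 * fs / max(f_lo, band$bw / 2))
    if (length(segment) < need)
      stop_field("segment too short for band fc = %g: need >= %d samples (10 cycles), got %d",
                 band$fc, need, length(segment))
  }
  n <- length(segment)
  x <- segment - mean(segment)
  freqs <- (seq_len(n %/% 2 + 1L) - 1L) * fs / n
  tapers <- vapply(seq_len(k), function(j)
    sqrt(2 / (n + 1)) * sin(pi * j * seq_len(n) / (n + 1)), numeric(n))
  sel <- if (is.null(band)) rep(TRUE, length(freqs)) else
    freqs >= band$fc - band$bw / 2 & freqs <= band$fc + band$bw / 2
  if (!any(sel)) stop_field("band contains no frequency bins for this segment length")

  per_taper <- vapply(seq_len(k), function(j) {
    X <- stats::fft(x * tapers[, j])[seq_along(freqs)]
    psd <- Mod(X)^2 / fs
    # one-sided: double all interior bins
    scale <- rep(2, length(freqs)); scale[1L] <- 1
    if (n %% 2L == 0L) scale[length(freqs)] <- 1
    sum(psd[sel] * scale[sel]) * fs / n
  }, numeric(1))

  est <- mean(per_taper)
  loo <- vapply(seq_len(k), function(j) mean(log(per_taper[-j])), numeric(1))
  se <- sqrt((k - 1) / k * sum((loo - mean(loo))^2))
  tq <- stats::qt(1 - (1 - conf) / 2, df = k - 1)
  ci <- exp(mean(log(per_taper)) + c(-1, 1) * tq * se)
  list(power = est, ci = ci, df_jackknife = k - 1, k = k, per_taper = per_taper)
}

# ---------------------------------------------------------------------------

#' Time-frequency response with baseline comparison and FDR mask
#'
#' Morlet spectrograms (fixed number of cycles per frequency) averaged over
#' an epoch set, expressed in dB relative to the mean baseline power per
#' frequency, with a per-pixel one-tailed paired t-test (epochs > baseline)
#' masked by Benjamini-Hochberg FDR.
#'
#' @param epochs numeric matrix, epochs x samples (stimulation-locked).
#' @param baseline_epochs numeric matrix of the same shape (sham/baseline).
#' @param fs sampling rate, Hz.
#' @param freqs frequencies of interest, Hz (default 5-25 Hz in 1-Hz steps).
#' @param n_cycles wavelet length in cycles at each frequency (default 6).
#' @param q FDR level for the significance mask.
#' @return list with `tfr_db` (freq x time, dB re baseline), `p`, `sig`
#'   (FDR mask), `freqs`, `times`.
#' @export
time_frequency_response <- function(epochs, baseline_epochs, fs,
                                    freqs = 5:25, n_cycles = 6, q = 0.05) {
  if (!is.matrix(epochs) || nrow(epochs) < 2L)
    stop_field("'epochs' must be a matrix with >= 2 epochs")
  if (!is.matrix(baseline_epochs) || nrow(baseline_epochs) < 2L)
    stop_field("'baseline_epochs' must be a matrix with >= 2 epochs")
  if (ncol(epochs) != ncol(baseline_epochs))
    stop_field("epoch lengths differ: %d vs %d samples",
               ncol(epochs), ncol(baseline_epochs))
  if (nrow(epochs) != nrow(baseline_epochs))
    stop_field("paired test needs equal epoch counts (%d vs %d)",
               nrow(epochs), nrow(baseline_epochs))

  nt <- ncol(epochs)
  pow_one <- function(X, f) {
    # n_cycles-cycle wavelet: FWHM bandwidth such that sigma_t = n_cycles/(2*pi*f)
    sigma_t <- n_cycles / (2 * pi * f)
    bw <- 2 * sqrt(2 * log(2)) / (2 * pi * sigma_t)
    band <- band_definition(f, bw)
    # epochs are typically shorter than the wavelet-support requirement of
    # morlet_bandpass; zero-pad symmetrically and crop (edge bias stays in
    # the pads)
    sup <- morlet_support(band, fs)
    pad <- max(0L, ceiling((3L * (2L * sup + 1L) + 1L - nt) / 2))
    Xp <- cbind(matrix(0, nrow(X), pad), X, matrix(0, nrow(X), pad))
    a <- morlet_bandpass(t(Xp), fs, band)
    t(Mod(a$values[(pad + 1L):(pad + nt), , drop = FALSE])^2)  # epochs x time
  }
  n_ep <- nrow(epochs)
  tfr <- array(NA_real_, c(length(freqs), nt))
  p <- array(NA_real_, c(length(freqs), nt))
  for (i in seq_along(freqs)) {
    ps <- pow_one(epochs, freqs[i])
    pb <- pow_one(baseline_epochs, freqs[i])
    base_mean <- mean(pb)
    tfr[i, ] <- 10 * log10(colMeans(ps) / base_mean)
    d <- ps - pb                               # paired differences per epoch
    md <- colMeans(d)
    sd_d <- sqrt(colSums(sweep(d, 2, md)^2) / (n_ep - 1))
    tstat <- md / (sd_d / sqrt(n_ep))
    p[i, ] <- stats::pt(tstat, df = n_ep - 1, lower.tail = FALSE)
  }
  qv <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p))
  list(tfr_db = tfr, p = p, sig = qv < q, freqs = freqs,
       times = (seq_len(nt) - 1L) / fs)
}
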