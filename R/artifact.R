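# Harmonic modeling of the sinusoidal stimulation artifact: the artifact is
# a periodic waveform (fundamental plus amplifier-induced harmonic
# distortion) that dwarfs the neural signal, so it is fit as a linear
# superposition of sines and cosines at multiples of a base frequency and
# subtracted; the fitted fundamental doubles as the stimulation phase
# reference.

#' Fit a harmonic series to a stimulation artifact
#'
#' Models the artifact as
#' \deqn{dc + \sum_{k=1}^{K} a_k \cos(2\pi k f_0 t) + b_k \sin(2\pi k f_0 t)}
#' with harmonics up to 40 Hz (`K = floor(40 / f0)`). Coefficients are
#' solved by least squares; the base frequency is refined by golden-section
#' search on residual variance within +/-1% of `f0_init`. Trapezoidal or
#' pulsed stimulation waveforms are broadband and cannot be modeled this
#' way; the fit refuses them explicitly.
#'
#' @param signal numeric vector, one channel (fit per channel per
#'   stimulation block — artifact amplitude varies with electrode distance).
#' @param fs sampling rate, Hz.
#' @param f0_init initial base frequency, Hz (0.75 or 1 in typical use).
#' @param refine_f0 logical; search for the base frequency (default TRUE).
#' @param max_harmonic_hz highest harmonic to include, Hz (default 40).
#' @param waveform `"sinusoidal"` (default). `"trapezoidal"` is refused:
#'   such blocks do not permit analysis during stimulation.
#' @return object of class `harmonic_fit`: `f0`, `k` (harmonic numbers),
#'   `a` (cosine), `b` (sine) coefficients, `dc`, `residual_ratio`
#'   (residual variance / total variance), `harmonic_residual_ratio`
#'   (residual variance at the harmonic frequencies only, the "poor
#'   removal" flag input), `converged`, `poor_removal` flag, `fs`, `n`.
#' @export
fit_harmonic_artifact <- function(signal, fs, f0_init, refine_f0 = TRUE,
                                  max_harmonic_hz = 40,
                                  waveform = c("sinusoidal", "trapezoidal")) {
  waveform <- match.arg(waveform)
  if (waveform == "trapezoidal")
    stop_field(paste("trapezoidal stimulation blocks do not permit analysis",
                     "during stimulation (broadband artifact); refusing to fit"))
  check_scalar_num(f0_init, "f0_init", lower = 1e-6)
  n <- length(signal)
  if (n < 10 * fs / f0_init)
    stop_field("need >= 10 periods of f0 (%g samples), got %d",
               ceiling(10 * fs / f0_init), n)
  K <- floor(max_harmonic_hz / f0_init)
  if (K < 1L) stop_field("no harmonic of f0 = %g below %g Hz", f0_init, max_harmonic_hz)
  if (K * f0_init >= fs / 2)
    stop_field("harmonic %d x %g Hz = %g Hz is at or above Nyquist (%g Hz)",
               K, f0_init, K * f0_init, fs / 2)
  tt <- (seq_len(n) - 1) / fs

  solve_at <- function(f0) {
    # harmonics built recursively from the fundamental phasor; normal
    # equations are well conditioned here (near-orthogonal sinusoid basis)
    X <- matrix(1, n, 2L * K + 1L)
    e1 <- exp(1i * 2 * pi * f0 * tt)
    ek <- rep(1 + 0i, n)
    for (k in seq_len(K)) {
      ek <- ek * e1
      X[, 2L * k] <- Re(ek)
      X[, 2L * k + 1L] <- Im(ek)
    }
    cf <- tryCatch(solve(crossprod(X), crossprod(X, signal)),
                   error = function(e) qr.coef(qr(X), signal))
    cf[is.na(cf)] <- 0
    res <- signal - X %*% cf
    list(coef = drop(cf), rss = sum(res^2), res = drop(res))
  }

  f0 <- f0_init
  converged <- TRUE
  if (refine_f0) {
    lo <- f0_init * 0.99; hi <- f0_init * 1.01
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- solve_at(x1)$rss; f2 <- solve_at(x2)$rss
    iter <- 0L
    while (hi - lo > 1e-6 * f0_init && iter < 80L) {
      if (f1 <= f2) { hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo); f1 <- solve_at(x1)$rss
      } else { lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo); f2 <- solve_at(x2)$rss
      }
      iter <- iter + 1L
    }
    f0 <- (lo + hi) / 2
    if (iter >= 80L) { converged <- FALSE; f0 <- f0_init }
    # if the boundary won, the optimum may lie outside the +/-1% window
    if (min(abs(f0 / f0_init - 0.99), abs(f0 / f0_init - 1.01)) < 1e-5) {
      converged <- FALSE
      warning("f0 search hit the +/-1% boundary; falling back to f0_init",
              call. = FALSE)
      f0 <- f0_init
    }
  }
  fit <- solve_at(f0)
  tot <- sum((signal - mean(signal))^2)
  residual_ratio <- if (tot > 0) fit$rss / tot else 0

  # residual power specifically at f0 and harmonics (narrow periodogram bins):
  # high values mean the periodic artifact was not captured (non-stationarity)
  res <- fit$res
  spec_res <- Mod(stats::fft(res))^2
  spec_sig <- Mod(stats::fft(signal - mean(signal)))^2
  hbins <- unique(pmin(n, round(seq_len(K) * f0 * n / fs) + 1L))
  halfw <- max(1L, round(f0 / 8 * n / fs))   # +/- f0/8 Hz: catches drift sidebands
  hwin <- unique(pmax(2L, pmin(n %/% 2, c(outer(hbins, -halfw:halfw, `+`)))))
  hr_num <- sum(spec_res[hwin]); hr_den <- sum(spec_sig[hwin])
  harmonic_residual_ratio <- if (hr_den > 0) hr_num / hr_den else 0

  structure(list(
    f0 = f0, k = seq_len(K),
    a = unname(fit$coef[2L * seq_len(K)]),
    b = unname(fit$coef[2L * seq_len(K) + 1L]),
    dc = unname(fit$coef[1L]),
    residual_ratio = residual_ratio,
    harmonic_residual_ratio = harmonic_residual_ratio,
    converged = converged,
    poor_removal = harmonic_residual_ratio > 0.2,
    fs = fs, n = n), class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf("<harmonic_fit> f0 = %.6g Hz, K = %d harmonics, fundamental amplitude %.3g\n",
              x$f0, length(x$k), sqrt(x$a[1]^2 + x$b[1]^2)))
  cat(sprintf("  residual/total variance = %.3g; at harmonics = %.3g%s\n",
              x$residual_ratio, x$harmonic_residual_ratio,
              if (x$poor_removal) "  [POOR REMOVAL]" else ""))
  invisible(x)
}

#' Reconstruct the fitted artifact waveform
#' @param model a `harmonic_fit`.
#' @param t times in seconds (defaults to the fitted sample grid).
#' @return numeric vector of the reconstruction.
#' @export
reconstruct_artifact <- function(model, t = NULL) {
  if (is.null(t)) t <- (seq_len(model$n) - 1) / model$fs
  out <- rep(model$dc, length(t))
  for (i in seq_along(model$k)) {
    w <- 2 * pi * model$k[i] * model$f0 * t
    out <- out + model$a[i] * cos(w) + model$b[i] * sin(w)
  }
  out
}

#' Subtract a fitted harmonic artifact from a signal
#'
#' @param signal numeric vector (same channel/block the model was fit on).
#' @param model a `harmonic_fit`.
#' @return numeric vector: `signal - reconstruction`.
#' @export
subtract_artifact <- function(signal, model) {
  signal - reconstruct_artifact(model, (seq_along(signal) - 1) / model$fs)
}

#' Stimulation phase from the fitted fundamental
#'
#' Phase of the fundamental component of a harmonic artifact fit, in
#' degrees, wrapped to (-180, 180]: 0 degrees at the positive peak of the
#' fitted fundamental (the anodal peak of the stimulation waveform),
#' increasing with time.
#'
#' @param model a `harmonic_fit`.
#' @param t times in seconds.
#' @return numeric vector of phases, degrees.
#' @export
stimulation_phase <- function(model, t) {
  amp <- sqrt(model$a[1]^2 + model$b[1]^2)
  if (amp <= 0 || !is.finite(amp))
    stop_field("fundamental amplitude is zero: no phase reference")
  # a*cos(wt)+b*sin(wt) = amp*cos(wt - phi0), phi0 = atan2(b, a);
  # phase relative to the positive peak is then wt - phi0
  phi0 <- atan2(model$b[1], model$a[1])
  wrap_phase(rad2deg(2 * pi * model$f0 * t - phi0))
}

#' Serialize / restore a harmonic fit as JSON
#' @param model a `harmonic_fit`.
#' @param path file path.
#' @return `path` invisibly; `read_harmonic_fit_json` returns the model.
#' @export
write_harmonic_fit_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_harmonic_fit_json
#' @export
read_harmonic_fit_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "harmonic_fit")
}
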