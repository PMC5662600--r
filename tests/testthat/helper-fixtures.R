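# Shared fixture builders. Everything is generated in code; no stored data.

# equally spaced phase grid on (-180, 180], n points
phase_grid <- function(n) seq(-180 + 360 / n, 180, by = 360 / n)

# minimal cycle table: C cycles of nper samples each, back to back
make_cycle_table <- function(C, nper, source = "tacs") {
  structure(data.frame(
    cycle = seq_len(C),
    start = seq(1L, by = nper, length.out = C),
    end = seq(nper, by = nper, length.out = C),
    source = source, retained = TRUE, reason = "",
    stringsAsFactors = FALSE),
    class = c("cycle_table", "data.frame"))
}

# per-sample phase ramp covering C cycles of nper samples (degrees)
ramp_phase <- function(C, nper) {
  rep(wrap_phase((seq_len(nper) - 0.5) / nper * 360), C)
}

# Hann-windowed sinusoidal burst added in place
add_burst <- function(x, fs, t0, dur, f, amp) {
  t <- (seq_along(x) - 1) / fs
  i <- which(t >= t0 & t < t0 + dur)
  tau <- t[i] - t0
  x[i] <- x[i] + amp * sin(2 * pi * f * tau) * 0.5 * (1 - cos(2 * pi * tau / dur))
  x
}

# von Mises sampler (Best & Fisher rejection scheme), radians
vm_draw <- function(n, kappa, mu = 0) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1]); f <- (1 + r * z) / (r + z); cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
    }
  }
  out
}

# brute-force modulation index: the independent one-liner oracle
mi_brute <- function(A, phi_deg) {
  z <- sum(A * exp(1i * phi_deg * pi / 180)) / length(A)
  list(r = Mod(z), phase = Arg(z) * 180 / pi)
}
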