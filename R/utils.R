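# Internal helpers: angle arithmetic, RNG scoping, input checks.

#' Wrap angles in degrees to the interval (-180, 180]
#'
#' The package-wide phase convention: 0 degrees is the positive peak of the
#' reference waveform, +/-180 degrees its trough; angles increase with time.
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector wrapped to (-180, 180].
#' @export
wrap_phase <- function(deg) {
  w <- deg %% 360
  ifelse(w > 180, w - 360, w)
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Absolute circular difference between two angles, degrees
#' @param a,b angles in degrees.
#' @return difference in [0, 180].
#' @export
circ_diff <- function(a, b) abs(wrap_phase(a - b))

# Unwrap a phase series given in radians.
unwrap_rad <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phi[1L], d))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic routine in the package funnels its draws through this so
# that identical seeds give bit-identical outputs.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation (keeps sub-streams independent per
# channel while staying inside 32-bit integer range).
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483587) + 1L
}

stop_field <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_field("'%s' must be a finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}
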