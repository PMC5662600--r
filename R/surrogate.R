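# Surrogate-based significance for PAC, FDR correction, circular tests,
# and cross-block consistency.

#' Phase-randomization surrogate test for the modulation index
#'
#' Builds the null distribution of the modulation index by incrementing
#' the low-frequency phase of each cycle by a random value uniformly
#' distributed in [0, 180) degrees — the same draw applied to every
#' electrode for that cycle, independent draws across cycles — and
#' recomputing r for each of `n_shuffles` randomizations. The p-value is
#' the rate at which surrogate r meets or exceeds the observed r, floored
#' at `1 / n_shuffles`.
#'
#' The input is the sufficient statistic: per-cycle complex sums of
#' z = A * exp(i*phi) (zeros for non-retained cycles), as produced inside
#' [run_pac_analysis()] or by the internal cycle accumulator.
#'
#' @param z_sums complex matrix, electrodes x cycles, of per-cycle sums of
#'   `A * exp(i*phi)` over retained samples (a vector is one electrode).
#' @param n_kept integer vector, total retained samples per electrode.
#' @param n_shuffles number of randomizations (default 10000).
#' @param seed RNG seed for the shuffle draws.
#' @param shift_range_deg width of the uniform phase-shift distribution,
#'   degrees; 180 by default (a 360 option exists for convention
#'   comparisons).
#' @return list with `p` (per electrode), `r_obs`, `n_shuffles`,
#'   `shift_range_deg`, `seed`.
#' @export
phase_randomization_test <- function(z_sums, n_kept, n_shuffles = 10000L,
                                     seed = NULL, shift_range_deg = 180) {
  if (is.vector(z_sums)) z_sums <- matrix(z_sums, nrow = 1L)
  E <- nrow(z_sums); C <- ncol(z_sums)
  if (length(n_kept) == 1L) n_kept <- rep(n_kept, E)
  if (length(n_kept) != E)
    stop_field("'n_kept' must have one entry per electrode")
  if (n_shuffles < 100L)
    warning("n_shuffles < 100: coarse p-value resolution", call. = FALSE)
  r_obs <- Mod(rowSums(z_sums)) / n_kept
  shifts <- with_seed(seed,
    matrix(stats::runif(C * n_shuffles, 0, deg2rad(shift_range_deg)),
           C, n_shuffles))
  rot <- exp(1i * shifts)
  r_sur <- Mod(z_sums %*% rot) / n_kept        # electrodes x shuffles
  # relative tolerance so exact rotation invariance (single retained cycle)
  # counts as a tie rather than falling to floating-point round-off
  exceed <- rowSums(r_sur >= r_obs * (1 - 1e-10))
  p <- pmax(exceed, 1) / n_shuffles
  list(p = p, r_obs = r_obs, n_shuffles = n_shuffles,
       shift_range_deg = shift_range_deg, seed = seed)
}

#' Benjamini-Hochberg FDR correction across electrodes
#'
#' Step-up FDR within one analysis block; by design no correction is
#' applied across blocks or frequency bands (blocks measure the stability
#' of an effect; bands are planned comparisons).
#'
#' @param p numeric vector of p-values.
#' @param q FDR level (default 0.05).
#' @return list with `significant` (logical mask), `q_values`, `q`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (length(p) == 0L)
    return(list(significant = logical(0), q_values = numeric(0), q = q))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_field("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(p, method = "BH")
  list(significant = !is.na(qv) & qv < q, q_values = qv, q = q)
}

#' Rayleigh test for circular non-uniformity
#'
#' Standard Rayleigh statistic Z = n * Rbar^2 with the usual finite-sample
#' approximation for the p-value.
#'
#' @param phases numeric vector of angles, degrees.
#' @return list with `rbar` (mean resultant length), `mean_phase`
#'   (degrees), `z`, `p`, `n`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 5L) stop_field("Rayleigh test needs n >= 5 (got %d)", n)
  zc <- mean(exp(1i * deg2rad(phases)))
  rbar <- Mod(zc)
  Z <- n * rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(rbar = rbar, mean_phase = wrap_phase(rad2deg(Arg(zc))),
       z = Z, p = min(max(p, 0), 1), n = n)
}

#' Cross-block consistency of entrainment
#'
#' Fraction of electrodes significant in at least `min_blocks` blocks —
#' the stability measure used to judge whether apparent entrainment
#' persists across repeated stimulation blocks or nights.
#'
#' @param masks list of named logical vectors, one per block
#'   (names = electrode ids), or a logical matrix electrodes x blocks.
#' @param min_blocks minimum number of significant blocks (default 2).
#' @return list with `consistent` (named logical per electrode),
#'   `fraction`, `n_blocks`.
#' @export
block_consistency <- function(masks, min_blocks = 2L) {
  if (is.matrix(masks))
    masks <- lapply(seq_len(ncol(masks)), function(j) {
      v <- masks[, j]
      if (is.null(names(v))) names(v) <- rownames(masks) %||% paste0("e", seq_along(v))
      v
    })
  if (length(masks) < 2L) stop_field("need >= 2 blocks")
  ids <- lapply(masks, names)
  common <- Reduce(intersect, ids)
  if (!all(vapply(ids, function(x) setequal(x, common), logical(1))))
    warning("electrode sets differ across blocks; intersecting", call. = FALSE)
  if (length(common) == 0L) stop_field("no common electrodes across blocks")
  counts <- Reduce(`+`, lapply(masks, function(m) as.integer(m[common])))
  consistent <- counts >= min_blocks
  names(consistent) <- common
  list(consistent = consistent, fraction = mean(consistent),
       n_blocks = length(masks))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
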