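# Cycle-wise phase-amplitude coupling: segment low-frequency cycles, screen
# them, equalize endogenous phase distributions, and compute the
# unnormalized modulation index r = |<A_HF(t) * exp(i*phi_LF(t))>|.

#' Segment a recording into low-frequency cycles
#'
#' One row per complete low-frequency cycle. Cycles can be defined from a
#' continuous phase series (endogenous slow oscillations or the fitted
#' stimulation-artifact phase) or from acoustic trigger times, where each
#' cycle starts at a trigger onset and lasts the mean inter-trigger
#' interval. Incomplete cycles at the boundaries are flagged `"edge"` and
#' not retained.
#'
#' @param phase numeric vector of instantaneous phase, degrees in
#'   (-180, 180], one value per sample; or `NULL` when using triggers.
#' @param triggers numeric vector of trigger onset times, seconds
#'   (monotone); or `NULL` when using a phase series.
#' @param fs sampling rate, Hz.
#' @param n_samples total number of samples in the recording (required for
#'   trigger mode; inferred from `phase` otherwise).
#' @param phase_source one of `"endogenous"`, `"tacs"`, `"acoustic"`;
#'   recorded per cycle and used by downstream filters.
#' @param min_cycles minimum number of complete cycles (default 10).
#' @return a `cycle_table`: data.frame with columns `cycle`, `start`, `end`
#'   (sample indices, inclusive), `source`, `retained`, `reason`. Trigger
#'   mode attaches a per-sample phase series (degrees; 0 at trigger onset)
#'   as attribute `"phase"`.
#' @export
segment_cycles <- function(phase = NULL, triggers = NULL, fs,
                           n_samples = NULL,
                           phase_source = c("endogenous", "tacs", "acoustic"),
                           min_cycles = 10L) {
  phase_source <- match.arg(phase_source)
  if (is.null(phase) == is.null(triggers))
    stop_field("provide exactly one of 'phase' or 'triggers'")

  if (!is.null(triggers)) {
    if (is.unsorted(triggers, strictly = TRUE))
      stop_field("'triggers' must be strictly increasing")
    if (is.null(n_samples)) stop_field("'n_samples' is required in trigger mode")
    if (length(triggers) < 2L)
      stop_field("insufficient data: need >= 2 triggers to define a cycle duration")
    iti <- mean(diff(triggers))
    dur <- round(iti * fs)
    start <- round(triggers * fs) + 1L
    end <- start + dur - 1L
    complete <- end <= n_samples & start >= 1L
    tab <- data.frame(cycle = seq_along(start), start = start, end = end,
                      source = phase_source,
                      retained = complete,
                      reason = ifelse(complete, "", "edge"),
                      stringsAsFactors = FALSE)
    tab <- tab[complete | TRUE, , drop = FALSE]
    if (sum(complete) < min_cycles)
      stop_field("insufficient data: %d complete cycles < %d", sum(complete), min_cycles)
    # per-sample phase ramp: 0 deg at onset, one full turn per mean ITI
    ph <- rep(NA_real_, n_samples)
    for (i in which(complete)) {
      idx <- tab$start[i]:tab$end[i]
      ph[idx] <- wrap_phase((idx - tab$start[i]) / dur * 360)
    }
    out <- structure(tab, class = c("cycle_table", "data.frame"))
    attr(out, "phase") <- ph
    attr(out, "mean_iti") <- iti
    return(out)
  }

  if (any(!is.finite(phase))) stop_field("'phase' contains non-finite values")
  n <- length(phase)
  phi <- unwrap_rad(deg2rad(phase))
  # enforce monotone cycle index against transient phase backtracking
  rel <- cummax(phi - phi[1L])
  dphi <- stats::median(diff(phi))
  idx <- floor((rel) / (2 * pi) + 1e-9)
  # number of complete cycles covered, counting each sample as dt of phase
  total <- (rel[n] + max(dphi, 0)) / (2 * pi)
  n_complete <- floor(total + 1e-9)
  starts <- c(1L, which(diff(idx) >= 1L) + 1L)
  starts <- starts[seq_len(min(length(starts), n_complete + 1L))]
  if (n_complete < 1L || length(starts) < 1L)
    stop_field("insufficient data: no complete low-frequency cycle")
  ends <- c(starts[-1L] - 1L, if (length(starts) == n_complete + 1L) NULL else n)
  starts <- starts[seq_len(n_complete)]
  ends <- ends[seq_len(n_complete)]
  if (n_complete < min_cycles)
    stop_field("insufficient data: %d complete cycles < %d", n_complete, min_cycles)
  structure(data.frame(cycle = seq_len(n_complete), start = starts, end = ends,
                       source = phase_source, retained = TRUE, reason = "",
                       stringsAsFactors = FALSE),
            class = c("cycle_table", "data.frame"))
}

# mean power of an amplitude series within each cycle
cycle_mean_power <- function(cycles, amplitude) {
  vapply(seq_len(nrow(cycles)), function(i) {
    if (!cycles$retained[i] && cycles$reason[i] == "edge") return(NA_real_)
    mean(amplitude[cycles$start[i]:cycles$end[i]]^2)
  }, numeric(1))
}

#' Reject cycles with outlier high-frequency power
#'
#' Patient movement and other broadband artifacts inflate the
#' high-frequency amplitude estimate; cycles whose mean HF power is an
#' outlier are dropped. Default rule: mean power > median + 2 * IQR across
#' all cycles (single pass — thresholds are computed once on all cycles,
#' not recomputed on the survivors). The strictly literal reading
#' (power > 2 * IQR) is available via `rule = "2iqr"`.
#'
#' @param cycles a `cycle_table`.
#' @param hf_amplitude numeric vector, instantaneous HF amplitude per sample.
#' @param rule `"median_2iqr"` (default) or `"2iqr"`.
#' @return the `cycle_table` with outlier cycles un-retained
#'   (`reason = "outlier power"`) and a `mean_hf_power` column added.
#' @export
reject_outlier_cycles <- function(cycles, hf_amplitude,
                                  rule = c("median_2iqr", "2iqr")) {
  rule <- match.arg(rule)
  if (nrow(cycles) < 10L) stop_field("need >= 10 cycles for outlier screening")
  pw <- cycle_mean_power(cycles, hf_amplitude)
  cycles$mean_hf_power <- pw
  ok <- cycles$retained & !is.na(pw)
  iqr <- stats::IQR(pw[ok])
  thr <- switch(rule, median_2iqr = stats::median(pw[ok]) + 2 * iqr,
                "2iqr" = 2 * iqr)
  # strict inequality: when all powers are equal (IQR = 0) nothing is rejected
  bad <- ok & pw > thr
  cycles$retained[bad] <- FALSE
  cycles$reason[bad] <- "outlier power"
  attr(cycles, "outlier_rule") <- rule
  attr(cycles, "outlier_threshold") <- thr
  cycles
}

#' Drop endogenous cycles with slow-oscillation amplitude below a floor
#'
#' During endogenous sleep, cycles where the slow-oscillation band
#' amplitude never reaches `floor` carry no usable phase and are excluded.
#' The criterion is the peak (maximum) SO-band amplitude within the cycle.
#' Not applicable to stimulation-defined cycles, whose phase comes from the
#' stimulus, not the signal.
#'
#' @param cycles a `cycle_table` with endogenous source.
#' @param so_amplitude numeric vector, instantaneous slow-oscillation-band
#'   amplitude per sample (same units as the floor).
#' @param floor amplitude floor, uV (default 50).
#' @return the `cycle_table` with sub-floor cycles un-retained
#'   (`reason = "low SO amplitude"`).
#' @export
amplitude_floor_filter <- function(cycles, so_amplitude, floor = 50) {
  if (any(cycles$source != "endogenous"))
    stop_field("amplitude floor applies to endogenous cycles only (got '%s')",
               setdiff(unique(cycles$source), "endogenous")[1L])
  peak <- vapply(seq_len(nrow(cycles)), function(i)
    max(so_amplitude[cycles$start[i]:cycles$end[i]]), numeric(1))
  bad <- cycles$retained & peak < floor
  cycles$retained[bad] <- FALSE
  cycles$reason[bad] <- "low SO amplitude"
  cycles$peak_so_amplitude <- peak
  cycles
}

#' Histogram equalization of a circular phase distribution
#'
#' Endogenous slow oscillations are non-sinusoidal, so their instantaneous
#' phase is not uniformly distributed in time; a non-zero modulation index
#' could then reflect phase dwell rather than amplitude coupling. The rank
#' transform maps the sorted phases onto equally spaced values around the
#' circle, anchored at the smallest sorted phase, preserving circular
#' order. An already-uniform grid is a fixed point. Stimulation-defined
#' phases are uniform by construction and must not be equalized.
#'
#' @param phase numeric vector of phases, degrees in (-180, 180].
#' @return numeric vector of equalized phases, degrees in (-180, 180],
#'   same order as the input.
#' @export
equalize_phase_histogram <- function(phase) {
  n <- length(phase)
  if (n == 0L) return(phase)
  ord <- order(phase)
  out <- numeric(n)
  out[ord] <- wrap_phase(phase[ord][1L] + 360 * (seq_len(n) - 1L) / n)
  out
}

#' Modulation index and preferred phase
#'
#' The unnormalized modulation index
#' \deqn{r = | \langle A(t) e^{i\phi(t)} \rangle |}
#' with the time average pooled over all retained samples (across cycles
#' and time within cycles), reported in amplitude units; the preferred
#' phase is the argument of the mean, degrees. A normalized companion
#' `r_norm = r / mean(A)` is returned for cross-channel comparison (for a
#' noise-free multiplicative coupling of depth d under uniform phase,
#' `r_norm = d / 2`).
#'
#' @param amplitude numeric vector A(t) over retained samples.
#' @param phase numeric vector phi(t), degrees, same length.
#' @return list with `r`, `preferred_phase` (degrees), `r_norm`, `n`.
#' @export
modulation_index <- function(amplitude, phase) {
  if (length(amplitude) == 0L) stop_field("empty input: no retained samples")
  if (length(amplitude) != length(phase))
    stop_field("amplitude and phase lengths differ (%d vs %d)",
               length(amplitude), length(phase))
  z <- mean(amplitude * exp(1i * deg2rad(phase)))
  list(r = Mod(z), preferred_phase = wrap_phase(rad2deg(Arg(z))),
       r_norm = Mod(z) / mean(amplitude), n = length(amplitude))
}

# Per-cycle complex sums of z = A * exp(i*phi) for the retained cycles:
# the sufficient statistic for both the observed modulation index and the
# cycle-shuffled surrogates. Returns list(sums = complex vector over ALL
# cycles (zeros where not retained), n = total retained samples).
cycle_z_sums <- function(cycles, amplitude, phase) {
  C <- nrow(cycles)
  sums <- complex(real = numeric(C))
  n <- 0L
  for (i in seq_len(C)) {
    if (!cycles$retained[i]) next
    idx <- cycles$start[i]:cycles$end[i]
    sums[i] <- sum(amplitude[idx] * exp(1i * deg2rad(phase[idx])))
    n <- n + length(idx)
  }
  list(sums = sums, n = n)
}

#' Export a cycle table for audit
#' @param cycles a `cycle_table`.
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_cycle_table <- function(cycles, path) {
  utils::write.table(as.data.frame(cycles), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
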