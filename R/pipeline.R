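# End-to-end orchestration: channel screening -> (artifact fit) -> band
# extraction -> cycle table -> filters -> equalization -> modulation index
# -> surrogate test -> FDR -> cross-block consistency, with provenance.

#' Screen channels for line noise, clipping, and poor artifact removal
#'
#' Per-channel quality flags: 60 Hz line-noise power ratio above threshold
#' (poor contact impedance), clipping fraction above threshold (amplifier
#' saturation), and — when harmonic artifact fits are supplied — residual
#' harmonic variance above the poor-removal threshold (non-stationary
#' stimulation artifact). Thresholds are package defaults recorded in the
#' output.
#'
#' @param rec a [ts_recording()].
#' @param artifact_fits optional list of `harmonic_fit`s, one per channel.
#' @param line_freq line frequency, Hz (default 60).
#' @param line_halfwidth half width of the line-noise band, Hz.
#' @param line_ratio_threshold discard when line-band power / total power
#'   exceeds this (default 0.5).
#' @param clip_threshold discard when the clipping fraction exceeds this
#'   (default 0.01).
#' @return data.frame: `channel`, `keep`, `reason` (`""`, `"line noise"`,
#'   `"clipping"`, `"poor artifact removal"`), `line_ratio`,
#'   `clip_fraction`.
#' @export
screen_channels <- function(rec, artifact_fits = NULL, line_freq = 60,
                            line_halfwidth = 2, line_ratio_threshold = 0.5,
                            clip_threshold = 0.01) {
  stopifnot(inherits(rec, "ts_recording"))
  n <- nrow(rec$data)
  freqs <- (seq_len(n %/% 2 + 1L) - 1L) * rec$fs / n
  line_bins <- abs(freqs - line_freq) <= line_halfwidth
  out <- lapply(seq_len(ncol(rec$data)), function(ch) {
    x <- rec$data[, ch]
    spec <- Mod(stats::fft(x - mean(x))[seq_along(freqs)])^2
    line_ratio <- if (sum(spec) > 0) sum(spec[line_bins]) / sum(spec) else 0
    rng <- range(x); span <- diff(rng)
    clip_fraction <- if (span == 0) 1 else
      mean(x > rng[2L] - 1e-3 * span | x < rng[1L] + 1e-3 * span)
    reason <- ""
    if (line_ratio > line_ratio_threshold) reason <- "line noise"
    else if (clip_fraction > clip_threshold) reason <- "clipping"
    else if (!is.null(artifact_fits) && isTRUE(artifact_fits[[ch]]$poor_removal))
      reason <- "poor artifact removal"
    data.frame(channel = rec$channels[ch], keep = reason == "",
               reason = reason, line_ratio = line_ratio,
               clip_fraction = clip_fraction, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full cycle-wise phase-amplitude coupling analysis
#'
#' Executes, per stimulation block: channel screening, harmonic artifact
#' fitting and subtraction (tACS), low-frequency phase extraction
#' (endogenous Morlet phase / fitted stimulation phase / acoustic trigger
#' ramp), high-frequency amplitude extraction, cycle segmentation, outlier
#' and amplitude-floor screening, phase-histogram equalization (endogenous
#' only), the modulation index, the shared-shuffle phase-randomization
#' surrogate test, Benjamini-Hochberg FDR across electrodes within the
#' block, and — across blocks — entrainment consistency.
#'
#' @param rec a [ts_recording()].
#' @param phase_source `"endogenous"`, `"tacs"`, or `"acoustic"`.
#' @param hf_band high-frequency [band_definition()] (default fast
#'   spindle (14, 7)).
#' @param lf_band low-frequency band for endogenous phase (default
#'   (1, 1)).
#' @param f_stim stimulation frequency, Hz (tACS mode).
#' @param triggers trigger times, seconds (acoustic mode).
#' @param blocks data.frame with `start`/`end` seconds; default one block
#'   spanning the recording.
#' @param n_shuffles surrogate randomizations (default 10000).
#' @param q FDR level.
#' @param amplitude_floor slow-oscillation amplitude floor, uV
#'   (endogenous; `NULL` disables).
#' @param outlier_rule outlier rule for [reject_outlier_cycles()].
#' @param equalize equalize the endogenous phase histogram (default TRUE;
#'   ignored for stimulation sources, which are uniform by construction).
#' @param screen run [screen_channels()] first (default TRUE).
#' @param min_cycles minimum complete cycles per block.
#' @param seed seed for the surrogate draws.
#' @return object of class `pac_analysis`: list with `results` (one row
#'   per electrode x block: `electrode`, `block`, `n_cycles`, `r`,
#'   `r_norm`, `preferred_phase`, `p`, `q_value`, `significant`),
#'   `screening`, `consistency` (for >= 2 blocks), `cycle_tables`,
#'   `artifact_fits`, `provenance`.
#' @export
run_pac_analysis <- function(rec, phase_source = c("endogenous", "tacs", "acoustic"),
                             hf_band = band_definition(14, 7),
                             lf_band = band_definition(1, 1),
                             f_stim = NULL, triggers = NULL, blocks = NULL,
                             n_shuffles = 10000L, q = 0.05,
                             amplitude_floor = 50,
                             outlier_rule = c("median_2iqr", "2iqr"),
                             equalize = TRUE, screen = TRUE,
                             min_cycles = 10L, seed = 1L) {
  stopifnot(inherits(rec, "ts_recording"))
  phase_source <- match.arg(phase_source)
  outlier_rule <- match.arg(outlier_rule)
  hf_band <- as_band(hf_band); lf_band <- as_band(lf_band)
  if (phase_source == "tacs" && is.null(f_stim))
    stop_field("'f_stim' is required for tACS analysis")
  if (phase_source == "acoustic" && is.null(triggers))
    stop_field("'triggers' are required for acoustic analysis")
  if (is.null(blocks))
    blocks <- data.frame(start = 0, end = rec_duration(rec))

  results <- list(); cycle_tables <- list(); artifact_fits <- list()
  screenings <- list(); masks <- list()

  for (b in seq_len(nrow(blocks))) {
    i0 <- floor(blocks$start[b] * rec$fs) + 1L
    i1 <- min(nrow(rec$data), round(blocks$end[b] * rec$fs))
    X <- rec$data[i0:i1, , drop = FALSE]
    nb <- nrow(X)
    tb <- (seq_len(nb) - 1) / rec$fs
    block_rec <- ts_recording(X, rec$fs, rec$channels)

    fits <- NULL
    if (phase_source == "tacs")
      fits <- lapply(seq_len(ncol(X)), function(ch)
        fit_harmonic_artifact(X[, ch], rec$fs, f_stim))
    scr <- if (screen) screen_channels(block_rec, artifact_fits = fits) else
      data.frame(channel = rec$channels, keep = TRUE, reason = "",
                 line_ratio = NA_real_, clip_fraction = NA_real_)
    screenings[[b]] <- cbind(block = b, scr)
    keep_idx <- which(scr$keep)
    if (length(keep_idx) == 0L) next

    z_rows <- list(); n_kept <- integer(0); row_meta <- list()
    for (ch in keep_idx) {
      x <- X[, ch]
      edge_n <- 0L
      if (phase_source == "tacs") {
        x <- subtract_artifact(x, fits[[ch]])
        phase <- stimulation_phase(fits[[ch]], tb)
        cyc <- segment_cycles(phase = phase, fs = rec$fs,
                              phase_source = "tacs", min_cycles = min_cycles)
        so_amp <- NULL
      } else if (phase_source == "endogenous") {
        lf <- morlet_bandpass(x, rec$fs, lf_band)
        phase <- inst_phase(lf)[, 1L]
        so_amp <- inst_amplitude(lf)[, 1L]
        edge_n <- lf$edge_samples
        cyc <- segment_cycles(phase = phase, fs = rec$fs,
                              phase_source = "endogenous",
                              min_cycles = min_cycles)
      } else {
        trig <- triggers[triggers >= blocks$start[b] & triggers < blocks$end[b]] -
          blocks$start[b]
        cyc <- segment_cycles(triggers = trig, fs = rec$fs, n_samples = nb,
                              phase_source = "acoustic",
                              min_cycles = min_cycles)
        phase <- attr(cyc, "phase")
        phase[is.na(phase)] <- 0   # outside cycles; never referenced
        so_amp <- NULL
      }
      hf <- morlet_bandpass(x, rec$fs, hf_band)
      amp <- inst_amplitude(hf)[, 1L]
      edge_n <- max(edge_n, hf$edge_samples)

      # flag cycles overlapping filter edges rather than silently keeping
      edge_bad <- cyc$retained &
        (cyc$start <= edge_n | cyc$end > nb - edge_n)
      cyc$retained[edge_bad] <- FALSE
      cyc$reason[edge_bad] <- "edge"

      cyc <- reject_outlier_cycles(cyc, amp, rule = outlier_rule)
      if (phase_source == "endogenous" && !is.null(amplitude_floor))
        cyc <- amplitude_floor_filter(cyc, so_amp, floor = amplitude_floor)

      use_phase <- phase
      if (phase_source == "endogenous" && equalize) {
        idx <- unlist(lapply(which(cyc$retained), function(i)
          cyc$start[i]:cyc$end[i]))
        use_phase[idx] <- equalize_phase_histogram(phase[idx])
      }

      zs <- cycle_z_sums(cyc, amp, use_phase)
      if (zs$n == 0L) next
      z_rows[[length(z_rows) + 1L]] <- zs$sums
      n_kept <- c(n_kept, zs$n)
      mi_idx <- unlist(lapply(which(cyc$retained), function(i)
        cyc$start[i]:cyc$end[i]))
      mi <- modulation_index(amp[mi_idx], use_phase[mi_idx])
      row_meta[[length(row_meta) + 1L]] <-
        data.frame(electrode = rec$channels[ch], block = b,
                   n_cycles = sum(cyc$retained), r = mi$r,
                   r_norm = mi$r_norm, preferred_phase = mi$preferred_phase,
                   stringsAsFactors = FALSE)
      cycle_tables[[paste0("block", b, "_", rec$channels[ch])]] <- cyc
    }
    if (length(z_rows) == 0L) next
    Cmax <- max(vapply(z_rows, length, integer(1)))
    Z <- t(vapply(z_rows, function(v) c(v, complex(real = numeric(Cmax - length(v)))),
                  complex(Cmax)))
    sur <- phase_randomization_test(Z, n_kept, n_shuffles = n_shuffles,
                                    seed = derive_seed(seed, b))
    fdr <- fdr_correct(sur$p, q = q)
    res <- do.call(rbind, row_meta)
    res$p <- sur$p
    res$q_value <- fdr$q_values
    res$significant <- fdr$significant
    results[[b]] <- res
    m <- fdr$significant; names(m) <- res$electrode
    masks[[length(masks) + 1L]] <- m
    if (phase_source == "tacs") artifact_fits[[b]] <- fits
  }

  if (length(results) == 0L) stop_field("no analyzable channels in any block")
  results <- do.call(rbind, results)
  consistency <- if (length(masks) >= 2L) block_consistency(masks) else NULL
  structure(list(
    results = results,
    screening = do.call(rbind, screenings),
    consistency = consistency,
    cycle_tables = cycle_tables,
    artifact_fits = if (length(artifact_fits)) artifact_fits,
    provenance = list(
      phase_source = phase_source,
      hf_band = unclass(hf_band), lf_band = unclass(lf_band),
      f_stim = f_stim, n_blocks = nrow(blocks), n_shuffles = n_shuffles,
      q = q, amplitude_floor = amplitude_floor, outlier_rule = outlier_rule,
      equalize = equalize, screen = screen, min_cycles = min_cycles,
      seed = seed,
      screening_thresholds = list(line_ratio = 0.5, clip_fraction = 0.01,
                                  harmonic_residual = 0.2),
      package_version = as.character(utils::packageVersion("ieegpac")))),
    class = "pac_analysis")
}

#' @export
print.pac_analysis <- function(x, ...) {
  cat(sprintf("<pac_analysis> %s phase, %d electrode x block results, %d significant (q < %g)\n",
              x$provenance$phase_source, nrow(x$results),
              sum(x$results$significant), x$provenance$q))
  if (!is.null(x$consistency))
    cat(sprintf("  consistent across >= 2 blocks: %.1f%% of electrodes\n",
                100 * x$consistency$fraction))
  invisible(x)
}

#' Write PAC results and provenance
#'
#' Results as a TSV (one row per electrode x block) and provenance —
#' configuration, seeds, thresholds, shuffle counts — as a JSON sidecar.
#'
#' @param x a `pac_analysis`.
#' @param path output TSV path; provenance goes to `<path>.provenance.json`.
#' @return `path` invisibly.
#' @export
write_pac_results <- function(x, path) {
  stopifnot(inherits(x, "pac_analysis"))
  utils::write.table(x$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(x$provenance, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
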