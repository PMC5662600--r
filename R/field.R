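# Electrode-level electric-field projection: the stimulation voltage at
# each electrode is the amplitude of a fitted sinusoid at the stimulation
# frequency; the projected field between adjacent electrodes is the
# potential difference divided by their distance, scaled to 1 mA.

#' Electrode geometry table
#'
#' @param id character electrode ids.
#' @param kind `"grid"`, `"strip"` or `"depth"` per electrode.
#' @param x,y,z 3-D positions, mm.
#' @param array array label (electrodes are only paired within the same
#'   array); defaults to the `kind` value.
#' @return data.frame of class `electrode_array`.
#' @export
electrode_array <- function(id, kind, x, y, z, array = kind) {
  kind <- match.arg(kind, c("grid", "strip", "depth"), several.ok = TRUE)
  if (!all(is.finite(c(x, y, z)))) stop_field("electrode positions must be finite")
  structure(data.frame(id = as.character(id), kind = kind, x = x, y = y, z = z,
                       array = as.character(array), stringsAsFactors = FALSE),
            class = c("electrode_array", "data.frame"))
}

#' Read electrode geometry from TSV (columns id, kind, x, y, z[, array])
#' @param path input path.
#' @return an `electrode_array`.
#' @export
read_geometry_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  electrode_array(df$id, df$kind, df$x, df$y, df$z,
                  array = if ("array" %in% names(df)) df$array else df$kind)
}

#' Estimate the stimulation voltage amplitude at one electrode
#'
#' Amplitude of the best-fit (least squares) sinusoid at the stimulation
#' frequency, phase free. Channels showing amplifier saturation (fraction
#' of samples within 0.1% of the extremes above `clip_tol`) are flagged
#' for exclusion.
#'
#' @param signal numeric vector, one channel during stimulation.
#' @param fs sampling rate, Hz.
#' @param f_stim stimulation frequency, Hz.
#' @param clip_tol clipping-fraction threshold (default 0.01).
#' @return list with `amplitude` (uV), `phase` (degrees, 0 at the positive
#'   peak relative to a cosine at t = 0), `clipped` (logical),
#'   `clip_fraction`.
#' @export
estimate_stim_voltage <- function(signal, fs, f_stim, clip_tol = 0.01) {
  n <- length(signal)
  if (n < 10 * fs / f_stim)
    stop_field("need >= 10 stimulation periods (%d samples), got %d",
               ceiling(10 * fs / f_stim), n)
  rng <- range(signal)
  span <- diff(rng)
  clip_fraction <- if (span == 0) 0 else
    mean(signal > rng[2L] - 1e-3 * span | signal < rng[1L] + 1e-3 * span)
  tt <- (seq_len(n) - 1) / fs
  X <- cbind(cos(2 * pi * f_stim * tt), sin(2 * pi * f_stim * tt))
  cf <- stats::lm.fit(X, signal - mean(signal))$coefficients
  amp <- sqrt(sum(cf^2))
  list(amplitude = amp,
       phase = if (amp > 0) wrap_phase(rad2deg(atan2(cf[2L], cf[1L]))) else NA_real_,
       clipped = clip_fraction > clip_tol, clip_fraction = clip_fraction)
}

#' Projected electric field between adjacent electrodes
#'
#' For each electrode, the closest electrode on the same array within a
#' kind-specific vicinity (10 mm for grid/strip, 5 mm for depth) defines a
#' pair; the projected field is the potential difference divided by the
#' Euclidean distance, converted to V/m and normalized to 1 mA of
#' stimulation current. Because magnitude fitting loses the voltage sign,
#' each electrode's relative phase (within 90 degrees of the stimulation
#' reference = positive, otherwise negative) restores it, so anti-phase
#' neighbors produce summed differences. The projection captures only the
#' field component along the pair axis, so values never exceed the true
#' field magnitude.
#'
#' @param amplitudes named numeric vector of fitted voltage amplitudes,
#'   uV (names = electrode ids).
#' @param geometry an [electrode_array()].
#' @param stim_current stimulation current the voltages were measured at,
#'   mA.
#' @param phases optional named numeric vector of fitted phases, degrees;
#'   when absent all amplitudes are treated as in-phase.
#' @param vicinity named numeric vector of adjacency limits, mm.
#' @return data.frame of class `field_projection`: `id`, `neighbor`,
#'   `distance_mm`, `v_uV` and `v_neighbor_uV` (signed), `field_V_per_m`
#'   (magnitude, scaled to 1 mA). Electrodes without a neighbor in the
#'   vicinity are omitted (listed in attribute `"omitted"`).
#' @export
projected_field <- function(amplitudes, geometry, stim_current = 1,
                            phases = NULL,
                            vicinity = c(grid = 10, strip = 10, depth = 5)) {
  check_scalar_num(stim_current, "stim_current", lower = .Machine$double.eps)
  ids <- geometry$id
  if (is.null(names(amplitudes)) || !all(ids %in% names(amplitudes)))
    stop_field("'amplitudes' must be named and cover every electrode in 'geometry'")
  signed <- amplitudes[ids]
  if (!is.null(phases)) {
    ph <- phases[ids]
    signed <- signed * ifelse(!is.na(ph) & abs(wrap_phase(ph)) > 90, -1, 1)
  }
  pos <- as.matrix(geometry[, c("x", "y", "z")])
  rows <- list(); omitted <- character(0)
  for (i in seq_along(ids)) {
    same <- which(geometry$array == geometry$array[i])
    same <- setdiff(same, i)
    if (length(same) == 0L) { omitted <- c(omitted, ids[i]); next }
    d <- sqrt(rowSums((pos[same, , drop = FALSE] -
                         matrix(pos[i, ], length(same), 3, byrow = TRUE))^2))
    lim <- vicinity[[geometry$kind[i]]]
    ok <- d <= lim
    if (!any(ok)) { omitted <- c(omitted, ids[i]); next }
    j <- same[ok][which.min(d[ok])]
    dist_mm <- min(d[ok])
    dv_uV <- abs(signed[i] - signed[j])
    # uV / mm = 1e-3 V/m; normalize to 1 mA
    rows[[length(rows) + 1L]] <- data.frame(
      id = ids[i], neighbor = ids[j], distance_mm = dist_mm,
      v_uV = unname(signed[i]), v_neighbor_uV = unname(signed[j]),
      field_V_per_m = unname(dv_uV / dist_mm * 1e-3 / stim_current))
  }
  if (length(omitted))
    message("electrodes without an adjacent neighbor omitted: ",
            paste(omitted, collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), neighbor = character(0),
               distance_mm = numeric(0), v_uV = numeric(0),
               v_neighbor_uV = numeric(0), field_V_per_m = numeric(0))
  attr(out, "omitted") <- omitted
  class(out) <- c("field_projection", "data.frame")
  out
}

#' Summary of projected fields (median and 5-95% box)
#' @param fields a `field_projection`.
#' @return list with `median`, `q05`, `q95`, `min`, `max`, `n`.
#' @export
field_summary <- function(fields) {
  v <- fields$field_V_per_m
  qs <- stats::quantile(v, c(0.05, 0.5, 0.95), names = FALSE)
  list(median = qs[2L], q05 = qs[1L], q95 = qs[3L],
       min = min(v), max = max(v), n = length(v))
}
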