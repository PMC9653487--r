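# Single-channel pressure-ramp recording analysis: unitary conductance from
# the current-amplitude histogram, first-activation pressures per amplitude
# class, and the calibrator/test tension-sensitivity ratio.
#
# A recording is a tibble (time_s, current_pA, pressure_mmHg) with attributes
# `sample_rate` (Hz), `voltage` (mV) and optional `ground_truth`.

new_recording <- function(time, current, pressure, sample_rate, voltage,
                          ground_truth = NULL) {
  stopifnot(length(time) == length(current), length(time) == length(pressure))
  out <- tibble(time_s = time, current_pA = current, pressure_mmHg = pressure)
  structure(out, class = c("patch_recording", class(out)),
            sample_rate = sample_rate, voltage = voltage,
            ground_truth = ground_truth)
}

#' @export
print.patch_recording <- function(x, ...) {
  cat(sprintf("<patch_recording> %.3g s at %g Hz, %g mV\n",
              nrow(x) / attr(x, "sample_rate"), attr(x, "sample_rate"),
              attr(x, "voltage")))
  NextMethod()
}

#' Write / read a recording as CSV with a JSON metadata sidecar
#'
#' The CSV holds `time_s`, `current_pA`, `pressure_mmHg`; the sidecar
#' (`<path>.json`) holds voltage, sample rate and any generation ground truth.
#'
#' @param r A `patch_recording`.
#' @param path CSV path.
#' @return `path` (write) or a `patch_recording` (read).
#' @export
write_recording <- function(r, path) {
  readr::write_csv(as_tibble(r), path)
  meta <- list(sample_rate = attr(r, "sample_rate"),
               voltage = attr(r, "voltage"),
               ground_truth = attr(r, "ground_truth"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_recording(d$time_s, d$current_pA, d$pressure_mmHg,
                sample_rate = meta$sample_rate, voltage = meta$voltage,
                ground_truth = meta$ground_truth)
}

# zero-phase 4th-order Butterworth lowpass (falls back to the raw trace when
# the cutoff is at or above Nyquist)
lowpass <- function(x, sample_rate, cutoff) {
  w <- 2 * cutoff / sample_rate
  if (w >= 1) return(x)
  bf <- signal::butter(4, w, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# dominant modes of the amplitude histogram by kernel-density maxima
amplitude_modes <- function(x, min_height_frac = 0.05) {
  d <- density(x, n = 2048)
  y <- d$y
  ismax <- y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf)
  keep <- ismax & y >= min_height_frac * max(y)
  tibble(level = d$x[keep], height = y[keep])
}

#' Estimate the unitary conductance of a recording
#'
#' Lowpass-filters the trace, finds the baseline and first open level as the
#' two lowest-amplitude dominant modes of the current histogram (kernel
#' density; the level of smaller magnitude is the baseline), and reports
#' `g = |open - baseline| / |V|`. The standard error comes from the spread of
#' per-event amplitudes after half-amplitude idealization.
#'
#' @param r A `patch_recording` with nonzero holding voltage.
#' @param filter_hz Lowpass cutoff, Hz (default 500).
#' @param min_separation Minimum baseline/open mode separation in pA;
#'   default `6 * sigma_noise` estimated from first differences.
#' @return A one-row tibble: `g_pS`, `se_pS`, `n_events`, `open_level_pA`,
#'   `baseline_pA`.
#' @export
estimate_unitary_conductance <- function(r, filter_hz = 500,
                                         min_separation = NULL) {
  voltage <- attr(r, "voltage")
  fs <- attr(r, "sample_rate")
  if (is.null(voltage) || voltage == 0) {
    abort("Recording has zero holding voltage", class = "mechgate_ephys_error")
  }
  x <- lowpass(r$current_pA, fs, filter_hz)
  sigma_noise <- mad(diff(r$current_pA)) / sqrt(2)
  min_separation <- min_separation %||% max(6 * sigma_noise, 1e-6)
  modes <- amplitude_modes(x)
  modes <- arrange(modes, abs(.data$level))
  if (nrow(modes) < 2) {
    abort("Current-amplitude histogram is unimodal: no resolvable openings",
          class = "mechgate_no_events_error")
  }
  baseline <- modes$level[1]   # smallest-magnitude dominant mode
  cand <- modes$level[abs(modes$level - baseline) >= min_separation]
  if (length(cand) == 0) {
    abort("No open level separated from baseline: no resolvable openings",
          class = "mechgate_no_events_error")
  }
  open_level <- cand[which.min(abs(cand - baseline))]  # first conductance step
  # refine both levels as local means around the density modes (the kernel
  # grid alone quantises levels at ~0.05 pA), using only slope-stable samples
  # so filter transients and step overshoot do not bias the levels
  sep <- abs(open_level - baseline)
  slope <- c(diff(x), 0)
  stable <- abs(slope) <= 3 * mad(slope) + 1e-9
  refine <- function(lv) {
    m <- abs(x - lv) <= sep / 4 & stable
    if (any(m)) median(x[m]) else lv
  }
  baseline <- refine(baseline)
  open_level <- refine(open_level)
  step_amp <- open_level - baseline
  # half-amplitude idealization for event-level amplitudes
  rel <- (x - baseline) / step_amp
  state <- rel > 0.5 & rel < 1.5   # sojourns at the first open level
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  op <- which(runs$values)
  amps <- vapply(op, function(i) mean(x[starts[i]:ends[i]]) - baseline, numeric(1))
  if (length(amps) == 0) {
    abort("No openings at the unitary level", class = "mechgate_no_events_error")
  }
  g_events <- abs(amps) / abs(voltage) * 1000        # pA/mV -> nS -> pS
  g <- abs(step_amp) / abs(voltage) * 1000
  tibble(g_pS = g,
         se_pS = if (length(g_events) > 1) sd(g_events) / sqrt(length(g_events)) else NA_real_,
         n_events = length(g_events),
         open_level_pA = open_level,
         baseline_pA = baseline)
}

#' Amplitude class band for a channel population
#'
#' The expected unitary current magnitude `g * |V|` bracketed by
#' `margin * noise_sd`. Bands for distinct conductances must not overlap.
#'
#' @param conductance_pS Unitary conductance, pS.
#' @param voltage_mV Holding voltage, mV.
#' @param noise_sd Trace noise standard deviation, pA.
#' @param margin Band half-width in noise SDs (default 3).
#' @return Numeric length-2 band (pA, magnitudes).
#' @export
amplitude_class <- function(conductance_pS, voltage_mV, noise_sd = 2, margin = 3) {
  amp <- conductance_pS * abs(voltage_mV) / 1000
  c(max(0, amp - margin * noise_sd), amp + margin * noise_sd)
}

# step events on a filtered trace: jump = difference of boxcar means over
# `window_s` on each side; events are contiguous |jump| >= threshold regions,
# each reported at its peak with the signed jump amplitude.
detect_steps <- function(x, fs, threshold, window_s = 0.005) {
  w <- max(2L, as.integer(round(window_s * fs)))
  n <- length(x)
  cs <- cumsum(c(0, x))
  jump <- rep(0, n)
  i <- (w + 1):(n - w)
  jump[i] <- (cs[i + w + 1] - cs[i + 1]) / w - (cs[i + 1] - cs[i + 1 - w]) / w
  above <- abs(jump) >= threshold
  if (!any(above)) return(tibble(index = integer(), amplitude = numeric()))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  on <- which(runs$values)
  rows <- lapply(on, function(k) {
    seg <- starts[k]:ends[k]
    j <- seg[which.max(abs(jump[seg]))]
    tibble(index = j, amplitude = jump[j])
  })
  list_rbind(rows)
}

#' Pressure at the first activation of a channel class
#'
#' Detects current steps on the lowpass-filtered trace (half-amplitude
#' criterion: detection threshold at half the lower band edge) and returns the
#' suction magnitude at the first upward step whose amplitude falls inside the
#' class band.
#'
#' @param r A `patch_recording` under a monotone pressure ramp.
#' @param amplitude_class Numeric length-2: expected step magnitude band, pA
#'   (see [amplitude_class()]).
#' @param filter_hz Lowpass cutoff, Hz.
#' @param ramp_tolerance Fraction of non-monotone pressure increments allowed.
#' @return Pressure magnitude in mmHg.
#' @export
first_activation_pressure <- function(r, amplitude_class, filter_hz = 500,
                                      ramp_tolerance = 0.01) {
  fs <- attr(r, "sample_rate")
  dp <- diff(abs(r$pressure_mmHg))
  if (mean(dp < -1e-9) > ramp_tolerance) {
    abort("Pressure is not a monotone ramp", class = "mechgate_ephys_error")
  }
  x <- lowpass(r$current_pA, fs, filter_hz)
  # channel already conducting in the class band at the trace start counts as
  # an activation at the first sample
  w <- max(2L, as.integer(round(0.005 * fs)))
  modes <- amplitude_modes(x)
  baseline <- modes$level[which.min(abs(modes$level))]
  init <- abs(mean(x[seq_len(min(w, length(x)))]) - baseline)
  if (init >= amplitude_class[1] && init <= amplitude_class[2]) {
    return(abs(r$pressure_mmHg[1]))
  }
  steps <- detect_steps(x, fs, threshold = amplitude_class[1] / 2)
  openings <- steps[abs(steps$amplitude) >= amplitude_class[1] &
                      abs(steps$amplitude) <= amplitude_class[2], , drop = FALSE]
  if (nrow(openings) == 0) {
    abort("No activation event in the amplitude class",
          class = "mechgate_no_activation_error")
  }
  abs(r$pressure_mmHg[openings$index[1]])
}

#' Tension-sensitivity ratio against an in-patch calibrator
#'
#' The ratio of the calibrator channel's first-activation pressure to the test
#' channel's (e.g. P_MscL / P_MscK): higher means the test channel opens at a
#' smaller fraction of the calibrator's threshold, i.e. is more
#' tension-sensitive.
#'
#' @param r A `patch_recording` containing both channel classes.
#' @param test_class,calibrator_class Amplitude bands (pA) for the test and
#'   calibrator channels (see [amplitude_class()]).
#' @param filter_hz Lowpass cutoff, Hz.
#' @return A one-row tibble: `p_first_test_mmHg`, `p_first_calibrator_mmHg`,
#'   `ratio`.
#' @export
tension_sensitivity_ratio <- function(r, test_class, calibrator_class,
                                      filter_hz = 500) {
  p_test <- first_activation_pressure(r, test_class, filter_hz = filter_hz)
  p_cal <- first_activation_pressure(r, calibrator_class, filter_hz = filter_hz)
  tibble(p_first_test_mmHg = p_test,
         p_first_calibrator_mmHg = p_cal,
         ratio = p_cal / p_test)
}

#' @export
autoplot.patch_recording <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("current_pA", "pressure_mmHg"),
                              names_to = "channel", values_to = "value")
  ggplot(long, aes(x = .data$time_s, y = .data$value)) +
    geom_line(...) +
    facet_wrap(~channel, scales = "free_y", ncol = 1) +
    labs(x = "time (s)", y = NULL, title = "Patch recording") +
    theme_bw()
}
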