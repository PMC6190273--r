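#' Low-pass filter specification
#'
#' The acquisition pipeline uses a second-order IIR Butterworth low-pass
#' filter with a 20 Hz cutoff at a 1 kHz sampling rate to remove
#' high-frequency physiological noise and motion artifacts while passing
#' the pulse waveform (fundamental ~1 Hz plus its first harmonics).
#'
#' @param order Filter order (default 2).
#' @param cutoff Cutoff frequency in Hz, must lie in `(0, fs/2)`.
#' @param fs Sampling rate in Hz.
#' @return A list of class `"filter_spec"`.
#' @export
filter_spec <- function(order = 2, cutoff = 20, fs = 1000) {
  stopifnot(order >= 1)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  structure(list(order = as.integer(order), cutoff = cutoff, fs = fs,
                 family = "butterworth_lowpass"),
            class = "filter_spec")
}

#' Butterworth low-pass filtering
#'
#' Digital Butterworth design (bilinear transform with cutoff
#' prewarping, via \pkg{signal}). Default is forward-only (causal)
#' filtering, matching a real-time embedded acquisition chain; bilateral
#' timing comparisons are unaffected by the causal group delay because
#' both channels incur it equally. `zero_phase = TRUE` applies the
#' filter forward and backward instead, preserving landmark times for
#' comparisons against absolute ground truth.
#'
#' @param x Numeric sample vector, longer than `3 * order`.
#' @param spec A [filter_spec()].
#' @param zero_phase Use forward-backward filtering?
#' @return Filtered vector of the same length.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' y <- butterworth_lowpass(sin(2 * pi * 5 * t) + rnorm(length(t), 0, 0.1))
#' @export
butterworth_lowpass <- function(x, spec = filter_spec(), zero_phase = FALSE) {
  if (length(x) == 0) stop("empty input")
  if (length(x) <= 3 * spec$order) stop("input shorter than 3 * filter order")
  bf <- signal::butter(spec$order, spec$cutoff / (spec$fs / 2), type = "low")
  if (zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Detect pulse feet
#'
#' A pulse foot is the local minimum at the onset of a beat's systolic
#' upstroke; foot-to-foot intervals define the beat windows. The
#' detector locates maxima of the smoothed first derivative (candidate
#' upstrokes) above a slope threshold, enforces a refractory period, and
#' takes the signal minimum in a short window preceding each upstroke.
#'
#' @param x Filtered sample vector, at least 2 s long.
#' @param fs Sampling rate in Hz.
#' @param slope_frac Slope threshold as a fraction of the smoothed
#'   derivative's 90th percentile (default 0.5).
#' @param refractory_s Minimum spacing between accepted upstrokes in
#'   seconds (default 0.25, i.e. a ceiling heart rate of 240 bpm).
#' @param smooth_s Moving-average width applied to the first derivative
#'   in seconds (default 0.025).
#' @param lookback_s Backward search window for the minimum preceding
#'   each upstroke, seconds (default 0.30).
#' @return Increasing integer vector of foot sample indices (1-based),
#'   one per detected beat; empty (with a warning) if no upstrokes are
#'   found.
#' @export
detect_pulse_feet <- function(x, fs = 1000, slope_frac = 0.5,
                              refractory_s = 0.25, smooth_s = 0.025,
                              lookback_s = 0.30) {
  if (length(x) < 2 * fs) stop("need at least 2 s of samples")
  dx <- diff(x)
  k <- max(1L, round(smooth_s * fs))
  dxs <- as.numeric(stats::filter(dx, rep(1 / k, k), sides = 2))
  dxs[is.na(dxs)] <- 0
  thr <- slope_frac * stats::quantile(dxs, 0.9, names = FALSE)
  if (!is.finite(thr) || thr <= 0 || max(dxs) <= 0) {
    warning("no systolic upstrokes found")
    return(integer(0))
  }
  above <- dxs > thr
  if (!any(above)) {
    warning("no systolic upstrokes found")
    return(integer(0))
  }
  # contiguous suprathreshold runs -> one derivative maximum each
  starts <- which(above & !c(FALSE, above[-length(above)]))
  ends <- which(above & !c(above[-1], FALSE))
  cand <- as.integer(mapply(function(s, e) s - 1L + which.max(dxs[s:e]),
                            starts, ends))
  # an upstroke needs a full backward search window of context to
  # anchor its foot; this also discards the causal filter's startup
  # transient, whose rise would otherwise mimic an upstroke
  cand <- sort(cand[cand > round(lookback_s * fs)])
  # refractory: greedily keep the earliest candidate of each cluster
  refr <- round(refractory_s * fs)
  keep <- integer(0)
  last <- -Inf
  for (ci in cand) {
    if (ci - last >= refr) { keep <- c(keep, ci); last <- ci }
  }
  lb <- as.integer(round(lookback_s * fs))
  feet <- vapply(keep, function(ci) {
    lo <- max(1L, ci - lb)
    as.integer(lo - 1L + which.min(x[lo:ci]))
  }, integer(1))
  feet <- feet[!duplicated(feet)]
  # physiologic bound check: drop feet implying intervals < 0.33 s
  if (length(feet) > 1) {
    ok <- c(TRUE, diff(feet) >= round(0.33 * fs))
    feet <- feet[ok]
  }
  sort(unique(feet))
}

#' Locate landmarks within one beat window
#'
#' Given two consecutive pulse-foot indices, locates the systolic peak
#' (window argmax, which must be interior) and the dicrotic notch (the
#' most prominent interior local minimum between the peak and 80\% of
#' the window; absent in damped pulses with no interior minimum).
#'
#' @param x Filtered sample vector.
#' @param foot_pair Two consecutive foot indices `c(start, end)`,
#'   half-open window `[start, end)`.
#' @param fs Sampling rate in Hz.
#' @return A list of class `"pulse_window"` with `start_index`,
#'   `end_index`, `foot_index`, `peak_index`, `notch_index` (`NA` if
#'   absent) and `amplitude` (peak minus foot value).
#' @export
detect_landmarks <- function(x, foot_pair, fs = 1000) {
  s <- as.integer(foot_pair[1]); e <- as.integer(foot_pair[2])
  if (length(foot_pair) != 2 || s >= e) stop("foot_pair must be ordered")
  if (s < 1 || e > length(x) + 1) stop("foot indices out of range")
  if ((e - s) / fs < 0.33) stop("beat window shorter than 0.33 s")
  seg <- x[s:(e - 1)]
  peak_rel <- which.max(seg)
  if (peak_rel == 1L || peak_rel == length(seg))
    stop("window maximum is a boundary sample; not a systolic peak")
  peak <- s - 1L + peak_rel
  # notch: most prominent local minimum in (peak, start + 0.8*window)
  hi_rel <- floor(0.8 * length(seg))
  notch <- NA_integer_
  if (hi_rel - peak_rel >= 3) {
    sub <- seg[peak_rel:hi_rel]
    n <- length(sub)
    is_min <- c(FALSE, sub[2:(n - 1)] < sub[1:(n - 2)] &
                       sub[2:(n - 1)] <= sub[3:n], FALSE)
    cand <- which(is_min)
    if (length(cand)) {
      # prominence: rise to the lower of the two flanking maxima
      prom <- vapply(cand, function(i) {
        left_max <- max(sub[1:i])
        right_max <- max(sub[i:n])
        min(left_max, right_max) - sub[i]
      }, numeric(1))
      notch <- s - 1L + (peak_rel - 1L) + cand[which.max(prom)]
    }
  }
  structure(list(start_index = s, end_index = e, foot_index = s,
                 peak_index = peak, notch_index = notch,
                 amplitude = x[peak] - x[s]),
            class = "pulse_window")
}

#' Segment a filtered channel into annotated beat windows
#'
#' Runs [detect_pulse_feet()] and [detect_landmarks()] over a whole
#' channel; beats whose window maximum is degenerate are dropped.
#'
#' @param x Filtered sample vector.
#' @param fs Sampling rate in Hz.
#' @param ... Passed to [detect_pulse_feet()].
#' @return A data.frame with one row per accepted beat: `foot_index`,
#'   `peak_index`, `notch_index`, `foot_time`, `peak_time`,
#'   `notch_time`, `rise_time` and `amplitude`.
#' @export
segment_channel <- function(x, fs = 1000, ...) {
  feet <- detect_pulse_feet(x, fs, ...)
  if (length(feet) < 2) {
    return(data.frame(foot_index = integer(0), peak_index = integer(0),
                      notch_index = integer(0), foot_time = numeric(0),
                      peak_time = numeric(0), notch_time = numeric(0),
                      rise_time = numeric(0), amplitude = numeric(0)))
  }
  rows <- lapply(seq_len(length(feet) - 1L), function(k) {
    w <- tryCatch(detect_landmarks(x, c(feet[k], feet[k + 1]), fs),
                  error = function(e) NULL)
    if (is.null(w)) return(NULL)
    data.frame(foot_index = w$foot_index, peak_index = w$peak_index,
               notch_index = w$notch_index,
               foot_time = (w$foot_index - 1) / fs,
               peak_time = (w$peak_index - 1) / fs,
               notch_time = if (is.na(w$notch_index)) NA_real_
                            else (w$notch_index - 1) / fs,
               rise_time = (w$peak_index - w$foot_index) / fs,
               amplitude = w$amplitude)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out
}

#' Filter and segment both channels of a PPG record
#'
#' Convenience wrapper: Butterworth-filters both channels with the same
#' specification and mode, then segments each into beat windows.
#'
#' @param record A [ppg_record()].
#' @param spec A [filter_spec()]; defaults to the standard 2nd-order
#'   20 Hz design at the record's sampling rate.
#' @param zero_phase Passed to [butterworth_lowpass()].
#' @param ... Passed to [detect_pulse_feet()].
#' @return A list with `right` and `left` beat tables (see
#'   [segment_channel()]) and the filtered signals `right_f`, `left_f`.
#' @export
preprocess_record <- function(record, spec = NULL, zero_phase = FALSE, ...) {
  if (is.null(spec)) spec <- filter_spec(fs = record$fs)
  rf <- butterworth_lowpass(record$right, spec, zero_phase)
  lf <- butterworth_lowpass(record$left, spec, zero_phase)
  list(right = segment_channel(rf, record$fs, ...),
       left = segment_channel(lf, record$fs, ...),
       right_f = rf, left_f = lf)
}
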