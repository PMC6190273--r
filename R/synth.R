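#' Pulse morphology parameters for the synthetic PPG generator
#'
#' Each synthetic beat is the sum of two log-normal-shaped lobes: a
#' systolic wave peaking `rise_time` seconds after the pulse foot, and a
#' smaller dicrotic wave whose separation from the systolic peak creates
#' a dicrotic notch. The shape is chosen for landmark identifiability
#' (foot, systolic peak and notch are all well defined), not as a
#' hemodynamic model.
#'
#' @param heart_rate Beats per minute, > 0.
#' @param systolic_amplitude Systolic peak amplitude, arbitrary units.
#' @param rise_time Foot-to-systolic-peak interval in seconds.
#' @param notch_delay Nominal systolic-peak-to-notch interval in seconds.
#' @param notch_depth Dicrotic lobe amplitude as a fraction of the
#'   systolic amplitude, strictly in (0, 1).
#' @param baseline_drift_amp Amplitude of a slow (0.25 Hz) baseline
#'   drift common to both channels, arbitrary units, >= 0.
#' @return A list of class `"pulse_shape_params"`.
#' @export
pulse_shape_params <- function(heart_rate = 72, systolic_amplitude = 1,
                               rise_time = 0.15, notch_delay = 0.25,
                               notch_depth = 0.35, baseline_drift_amp = 0.02) {
  stopifnot(heart_rate > 0, systolic_amplitude > 0, rise_time > 0,
            notch_delay > 0, baseline_drift_amp >= 0)
  if (notch_depth <= 0 || notch_depth >= 1)
    stop("notch_depth must be strictly between 0 and 1")
  if (rise_time + notch_delay >= 60 / heart_rate)
    stop("rise_time + notch_delay must be shorter than the beat period")
  structure(list(heart_rate = heart_rate,
                 systolic_amplitude = systolic_amplitude,
                 rise_time = rise_time, notch_delay = notch_delay,
                 notch_depth = notch_depth,
                 baseline_drift_amp = baseline_drift_amp),
            class = "pulse_shape_params")
}

#' Inter-arm asymmetry parameters
#'
#' A unilateral fistula stenosis makes the two arms' pulses progressively
#' asynchronous: the affected side's pulse foot arrives later, rises more
#' slowly, is damped in amplitude, and its dicrotic notch shifts. These
#' four parameters encode that asymmetry (right channel relative to
#' left). A zero-asymmetry instance (`0, 0, 1, 0`) produces identical
#' channels up to jitter.
#'
#' @param foot_delay Right-minus-left pulse-foot time offset, seconds.
#' @param rise_time_skew Additional right-channel rise time, seconds.
#' @param amplitude_ratio Right/left systolic amplitude ratio, > 0.
#' @param notch_shift Additional right-channel notch delay, seconds.
#' @return A list of class `"asymmetry_params"`.
#' @export
asymmetry_params <- function(foot_delay = 0, rise_time_skew = 0,
                             amplitude_ratio = 1, notch_shift = 0) {
  vals <- c(foot_delay, rise_time_skew, amplitude_ratio, notch_shift)
  if (any(!is.finite(vals))) stop("asymmetry parameters must be finite")
  if (amplitude_ratio <= 0) stop("amplitude_ratio must be > 0")
  structure(list(foot_delay = foot_delay, rise_time_skew = rise_time_skew,
                 amplitude_ratio = amplitude_ratio, notch_shift = notch_shift),
            class = "asymmetry_params")
}

#' Default coupling from degree of stenosis to inter-arm asymmetry
#'
#' Deterministic monotone maps sized so the three DOS classes are
#' separable but overlapping under physiologic jitter: each timing
#' asymmetry grows linearly with DOS and the affected side's amplitude is
#' progressively damped.
#'
#' @param dos DOS fraction in \code{[0, 1]}.
#' @param coef Named list of coupling coefficients:
#'   `foot_delay` (s per unit DOS, default 0.08), `rise_time_skew`
#'   (default 0.05 s), `amplitude_loss` (fractional amplitude loss at
#'   full occlusion, default 0.4), `notch_shift` (default 0.03 s).
#' @return An [asymmetry_params()] object.
#' @export
asymmetry_from_dos <- function(dos,
                               coef = list(foot_delay = 0.08,
                                           rise_time_skew = 0.05,
                                           amplitude_loss = 0.4,
                                           notch_shift = 0.03)) {
  if (dos < 0 || dos > 1) stop("dos must lie in [0, 1]")
  asymmetry_params(foot_delay = coef$foot_delay * dos,
                   rise_time_skew = coef$rise_time_skew * dos,
                   amplitude_ratio = 1 - coef$amplitude_loss * dos,
                   notch_shift = coef$notch_shift * dos)
}

#' Per-subject physiologic jitter parameters
#'
#' Zero-mean beat-to-beat variability applied on top of the deterministic
#' asymmetry: beat-period jitter (coefficient of variation), landmark
#' timing jitter (SD, applied independently per channel to foot time,
#' rise time and notch delay) and amplitude jitter (CV).
#' `jitter_off()` disables all three, giving fully deterministic
#' waveforms for landmark ground-truth tests.
#'
#' @param period_cv Beat-period coefficient of variation (default 0.02).
#' @param landmark_sd Landmark timing jitter SD in seconds (default 0.005).
#' @param amplitude_cv Amplitude coefficient of variation (default 0.03).
#' @return A list of class `"jitter_params"`.
#' @export
jitter_params <- function(period_cv = 0.02, landmark_sd = 0.005,
                          amplitude_cv = 0.03) {
  stopifnot(period_cv >= 0, landmark_sd >= 0, amplitude_cv >= 0)
  structure(list(period_cv = period_cv, landmark_sd = landmark_sd,
                 amplitude_cv = amplitude_cv),
            class = "jitter_params")
}

#' @rdname jitter_params
#' @export
jitter_off <- function() jitter_params(0, 0, 0)

# Log-normal lobe: unit peak exactly at u = tp, support u > 0.
lognormal_lobe <- function(u, tp, w) {
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- exp(-(log(u[pos] / tp))^2 / (2 * w^2))
  out
}

# One beat evaluated at time u (s) after its foot. Systolic lobe
# (log-width 0.35) peaks near `rise`; dicrotic lobe (log-width 0.25,
# amplitude depth*amp) peaks at rise + 1.5*notch_delay, leaving a local
# minimum (the notch) between the two peaks.
beat_wave <- function(u, amp, rise, notch_delay, depth) {
  amp * (lognormal_lobe(u, rise, 0.35) +
         depth * lognormal_lobe(u, rise + 1.5 * notch_delay, 0.25))
}

#' Construct a two-channel PPG record
#'
#' @param subject_id Character id.
#' @param right,left Equal-length numeric sample vectors.
#' @param fs Sampling rate in Hz (1000 by default; the acquisition
#'   model assumes synchronous 1 kHz sampling of both thumbs).
#' @param annotations Optional list with elements `right` and `left`,
#'   each a per-beat data.frame of ground-truth landmark times (only
#'   available for synthetic records).
#' @return A list of class `"ppg_record"`.
#' @export
ppg_record <- function(subject_id, right, left, fs = 1000,
                       annotations = NULL) {
  if (length(right) != length(left))
    stop("right and left channels must have identical length")
  structure(list(subject_id = as.character(subject_id), fs = fs,
                 right = as.numeric(right), left = as.numeric(left),
                 duration = length(right) / fs,
                 annotations = annotations),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("PPG record %s: %.1f s at %g Hz (%d samples/channel)%s\n",
              x$subject_id, x$duration, x$fs, length(x$right),
              if (is.null(x$annotations)) "" else ", with ground-truth annotations"))
  invisible(x)
}

# Render one channel and its ground-truth landmark annotations.
# onsets: nominal beat-onset times shared by both channels (s, may start
# before 0 so the record opens mid-pulsation); per-beat parameter vectors
# are channel-specific.
render_channel <- function(t, onsets, rises, notch_delays, amps, depth,
                           fs, duration) {
  x <- numeric(length(t))
  n_beats <- length(onsets)
  for (k in seq_len(n_beats)) {
    lo <- max(1L, floor((onsets[k]) * fs) + 1L)
    hi <- min(length(t), ceiling((onsets[k] + 2.0) * fs))
    if (lo > hi) next
    idx <- lo:hi
    x[idx] <- x[idx] + beat_wave(t[idx] - onsets[k], amps[k], rises[k],
                                 notch_delays[k], depth)
  }
  # ground truth for beats fully inside the record, located numerically
  # on the composite waveform (lobe overlap shifts landmarks slightly
  # from their nominal construction values)
  ann <- list()
  for (k in seq_len(n_beats)) {
    o <- onsets[k]
    period <- if (k < n_beats) onsets[k + 1] - o else NA_real_
    if (o < 0.05 || is.na(period) || o + period > duration) next
    win <- function(a, b) {
      ia <- max(1L, round(a * fs) + 1L); ib <- min(length(t), round(b * fs) + 1L)
      ia:ib
    }
    fw <- win(o - 0.12, o + 0.6 * rises[k])
    foot_i <- fw[which.min(x[fw])]
    pw <- win(o + 0.25 * rises[k], o + 0.45 * period)
    peak_i <- pw[which.max(x[pw])]
    dic_t <- o + rises[k] + 1.5 * notch_delays[k]
    nw <- win(t[peak_i] + 0.005, dic_t - 0.005)
    notch_i <- if (length(nw) > 2) nw[which.min(x[nw])] else NA_integer_
    ann[[length(ann) + 1L]] <- data.frame(
      beat = k, foot_time = t[foot_i], peak_time = t[peak_i],
      notch_time = if (is.na(notch_i)) NA_real_ else t[notch_i],
      amplitude = x[peak_i] - x[foot_i])
  }
  list(x = x, annotations = do.call(rbind, ann))
}

#' Generate one synthetic bilateral PPG subject
#'
#' Produces a two-channel quasi-periodic PPG record whose inter-arm
#' asynchrony is a deterministic monotone function of the degree of
#' stenosis (see [asymmetry_from_dos()]), plus zero-mean per-beat jitter
#' controlled by `seed`. The returned metadata carries a diameter pair
#' consistent with `dos` via the DOS formula (`D = 1.0`,
#' `d = sqrt(1 - dos)`), and both channels carry numerically located
#' ground-truth landmark annotations for detector validation.
#'
#' @param dos DOS fraction in \code{[0, 1]}.
#' @param shape [pulse_shape_params()].
#' @param duration Record length in seconds; must cover at least five
#'   beat periods.
#' @param seed Integer seed controlling all jitter and demographics.
#' @param jitter [jitter_params()]; use [jitter_off()] for deterministic
#'   waveforms.
#' @param asymmetry Optional [asymmetry_params()] overriding the default
#'   DOS coupling (used for controlled single-asymmetry experiments).
#' @param subject_id Character id (default derived from the seed).
#' @param fs Sampling rate, Hz.
#' @return A list with elements `record` ([ppg_record()]) and `meta`
#'   ([subject_meta()]).
#' @examples
#' subj <- generate_subject(dos = 0.4, seed = 1)
#' subj$meta
#' @export
generate_subject <- function(dos, shape = pulse_shape_params(),
                             duration = 10, seed = 1,
                             jitter = jitter_params(), asymmetry = NULL,
                             subject_id = sprintf("synth-%d", seed),
                             fs = 1000) {
  if (dos < 0 || dos > 1) stop("dos must lie in [0, 1]")
  period <- 60 / shape$heart_rate
  if (duration < 5 * period)
    stop("duration must cover at least five beat periods")
  if (is.null(asymmetry)) asymmetry <- asymmetry_from_dos(dos)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # shared beat schedule; starts one period early so the record opens
  # mid-pulsation and the first in-record foot has a preceding tail
  n_beats <- ceiling((duration + 2 * period) / (period * 0.9)) + 2L
  periods <- period * (1 + stats::rnorm(n_beats, 0, jitter$period_cv))
  periods <- pmax(periods, 0.33)
  onsets <- cumsum(c(-1.2 * period, periods[-n_beats]))
  onsets <- onsets[onsets < duration]
  n_beats <- length(onsets)

  t <- seq(0, by = 1 / fs, length.out = round(fs * duration))
  jt <- function(n, sd) stats::rnorm(n, 0, sd)

  chans <- list()
  for (ch in c("left", "right")) {
    delay <- if (ch == "right") asymmetry$foot_delay else 0
    rise0 <- shape$rise_time +
      if (ch == "right") asymmetry$rise_time_skew else 0
    nd0 <- shape$notch_delay +
      if (ch == "right") asymmetry$notch_shift else 0
    amp0 <- shape$systolic_amplitude *
      if (ch == "right") asymmetry$amplitude_ratio else 1
    ch_onsets <- onsets + delay + jt(n_beats, jitter$landmark_sd)
    rises <- pmax(rise0 + jt(n_beats, jitter$landmark_sd), 0.04)
    nds <- pmax(nd0 + jt(n_beats, jitter$landmark_sd), 0.05)
    amps <- pmax(amp0 * (1 + jt(n_beats, jitter$amplitude_cv)), 0.05 * amp0)
    chans[[ch]] <- render_channel(t, ch_onsets, rises, nds, amps,
                                  shape$notch_depth, fs, duration)
  }

  drift_phase <- stats::runif(1, 0, 2 * pi)
  drift <- shape$baseline_drift_amp * sin(2 * pi * 0.25 * t + drift_phase)

  rec <- ppg_record(subject_id,
                    right = chans$right$x + drift,
                    left = chans$left$x + drift,
                    fs = fs,
                    annotations = list(right = chans$right$annotations,
                                       left = chans$left$annotations))
  age <- round(min(95, max(30, stats::rnorm(1, 69.4, 13.1))))
  gender <- sample(c("male", "female"), 1, prob = c(0.7, 0.3))
  meta <- subject_meta(subject_id, d = sqrt(1 - dos), D = 1.0,
                       dos_value = dos, age = age, gender = gender)
  list(record = rec, meta = meta)
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default DOS sampling bands of the three severity classes
#'
#' Class 1 subjects are drawn from DOS 5--30\%, class 2 from 30--50\%,
#' class 3 from 50--85\% (near-total occlusions, where the affected arm's
#' pulse would be barely detectable, are not simulated).
#'
#' @return A list of three `c(lo, hi)` DOS intervals.
#' @export
default_class_bands <- function() {
  list(c(0.05, 0.30), c(0.30, 0.50), c(0.50, 0.85))
}

#' Generate a synthetic bilateral-PPG cohort
#'
#' Draws `n_per_class` subjects per severity class with DOS sampled
#' uniformly within each class band, and generates each subject's record
#' with [generate_subject()]. Class labels are assigned from the drawn
#' DOS via [dos_to_class()]. Fully reproducible under a fixed seed.
#'
#' @param n_per_class Subjects per class, >= 1.
#' @param class_dos_ranges List of three `c(lo, hi)` DOS intervals within
#'   `[0, 1]`.
#' @param seed Integer master seed.
#' @param duration,shape,jitter,fs Passed to [generate_subject()].
#' @return A list of class `"ppg_cohort"`: one `list(record, meta)` per
#'   subject, 3 * `n_per_class` in total.
#' @export
generate_cohort <- function(n_per_class, class_dos_ranges = default_class_bands(),
                            seed = 1, duration = 10,
                            shape = pulse_shape_params(),
                            jitter = jitter_params(), fs = 1000) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (length(class_dos_ranges) != 3)
    stop("class_dos_ranges must list three DOS intervals")
  for (b in class_dos_ranges) {
    if (length(b) != 2 || b[1] >= b[2] || b[1] < 0 || b[2] > 1)
      stop("each DOS interval must be increasing and within [0, 1]")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_total <- 3L * n_per_class
  dos_draws <- unlist(lapply(class_dos_ranges,
                             function(b) stats::runif(n_per_class, b[1], b[2])))
  subj_seeds <- sample.int(.Machine$integer.max, n_total)
  cohort <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cohort[[i]] <- generate_subject(dos = dos_draws[i], shape = shape,
                                    duration = duration,
                                    seed = subj_seeds[i], jitter = jitter,
                                    subject_id = sprintf("synth-%03d", i),
                                    fs = fs)
  }
  structure(cohort, class = "ppg_cohort")
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cls <- vapply(x, function(s) s$meta$true_class, integer(1))
  cat(sprintf("Synthetic PPG cohort: %d subjects (classes: %s)\n",
              length(x), paste(table(cls), collapse = "/")))
  invisible(x)
}

#' Summarise a cohort as a manifest data.frame
#'
#' @param cohort A `"ppg_cohort"` (see [generate_cohort()]).
#' @return Data.frame with columns `subject_id, d, D, dos, age, gender,
#'   class`.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    m <- s$meta
    data.frame(subject_id = m$subject_id, d = m$d, D = m$D, dos = m$dos,
               age = m$age, gender = m$gender, class = m$true_class,
               stringsAsFactors = FALSE)
  }))
}

#' Add calibrated noise at a target SNR
#'
#' Adds zero-mean noise scaled so that the realised signal-to-noise
#' ratio `10*log10(P_signal / P_noise)` equals `snr_db` exactly, where
#' `P_signal` is the mean squared value of the mean-removed signal and
#' `P_noise` the mean squared value of the generated noise. The noise
#' vector is rescaled to its own realised power, so the empirical SNR
#' matches the target irrespective of the draw.
#'
#' Two noise constructions are available:
#' \describe{
#'   \item{`"white"`}{white Gaussian noise (the default). Note that
#'     white noise is mostly out-of-band for a PPG pipeline: the 20 Hz
#'     low-pass front end removes ~97\% of its power, so the effective
#'     in-band SNR is far higher than `snr_db`.}
#'   \item{`"surrogate"`}{noise constructed from the signal itself: a
#'     phase-randomized surrogate sharing the signal's amplitude
#'     spectrum. Being spectrally matched, it survives the low-pass
#'     front end, so `snr_db` is also the in-band SNR. This is the
#'     construction the noise-robustness protocol uses.}
#' }
#'
#' @param x Numeric signal with nonzero power after mean removal.
#' @param snr_db Target SNR in dB; `Inf` is the "clean" sentinel and
#'   returns `x` unchanged.
#' @param seed Integer seed for the noise draw.
#' @param type `"white"` or `"surrogate"`.
#' @return The noisy signal, same length as `x`.
#' @export
add_noise <- function(x, snr_db, seed = 1, type = c("white", "surrogate")) {
  type <- match.arg(type)
  if (!is.finite(snr_db)) {
    if (is.na(snr_db) || snr_db != Inf)
      stop("snr_db must be a finite dB value or +Inf (clean sentinel)")
    return(x)
  }
  xc <- x - mean(x)
  p_sig <- mean(xc^2)
  if (p_sig <= 0) stop("signal has zero power; SNR undefined")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  w <- if (type == "white") {
    stats::rnorm(length(x))
  } else {
    # randomize the phases of the signal's own spectrum; taking the
    # real part yields real noise with the same amplitude spectrum
    # shape (power rescaled below anyway)
    ph <- exp(2i * pi * stats::runif(length(x)))
    w0 <- Re(stats::fft(stats::fft(xc) * ph, inverse = TRUE)) / length(x)
    w0 - mean(w0)
  }
  p_target <- p_sig / 10^(snr_db / 10)
  w <- w * sqrt(p_target / mean(w^2))
  x + w
}

#' @description `add_noise_record()` applies [add_noise()] independently
#'   to both channels of a [ppg_record()] (distinct sub-seeds per
#'   channel), preserving the ground-truth annotations of the clean
#'   waveform.
#' @param record A [ppg_record()].
#' @rdname add_noise
#' @export
add_noise_record <- function(record, snr_db, seed = 1,
                             type = c("white", "surrogate")) {
  type <- match.arg(type)
  r2 <- record
  r2$right <- add_noise(record$right, snr_db, seed = seed, type = type)
  r2$left <- add_noise(record$left, snr_db, seed = seed + 1L, type = type)
  r2
}

#' Write / read a two-column PPG CSV
#'
#' Plain numeric CSV, columns `right, left`, one row per sample. By
#' default no header row is written; `header = TRUE` adds one.
#'
#' @param record A [ppg_record()].
#' @param path Output path.
#' @param header Write a header row?
#' @return `write_ppg_csv()` invisibly returns `path`; `read_ppg_csv()`
#'   returns a [ppg_record()] (without annotations).
#' @export
write_ppg_csv <- function(record, path, header = FALSE) {
  df <- data.frame(right = record$right, left = record$left)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}

#' @param fs Sampling rate of the stored record, Hz.
#' @param subject_id Id to attach to the loaded record.
#' @rdname write_ppg_csv
#' @export
read_ppg_csv <- function(path, fs = 1000, subject_id = basename(path)) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = has_header)
  if (ncol(df) < 2) stop("PPG CSV must have two columns (right, left)")
  ppg_record(subject_id, right = df[[1]], left = df[[2]], fs = fs)
}
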