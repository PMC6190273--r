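#' Bilateral difference pattern
#'
#' The element-wise absolute difference between the synchronously
#' sampled right and left channels, `d_i = |xR_i - xL_i|`, collected as
#' the difference pattern `Phi = [d_1, ..., d_n]`. Symmetric in its
#' arguments.
#'
#' @param xR,xL Equal-length numeric sample vectors.
#' @return Numeric vector of non-negative differences, class
#'   `"difference_pattern"`.
#' @examples
#' bilateral_difference(c(3, 5, 2), c(1, 2, 4))
#' @export
bilateral_difference <- function(xR, xL) {
  if (length(xR) != length(xL)) stop("channel lengths differ")
  if (length(xR) < 1) stop("empty input")
  structure(abs(xR - xL), class = "difference_pattern")
}

#' Extract the four bilateral asynchrony features
#'
#' For every pair of beats matched across the channels (nearest foot
#' times within half the median beat period), computes the absolute
#' left-right asymmetry of four pulse landmarks, then aggregates across
#' beats by the median:
#' \describe{
#'   \item{d1}{foot-time difference (s), the pulse-arrival asynchrony;}
#'   \item{d2}{systolic-peak-time difference (s), the pulse-transit-time
#'     asymmetry;}
#'   \item{d3}{rise-time difference (s), rise time being the
#'     foot-to-peak interval per channel;}
#'   \item{d4}{normalized amplitude difference (dimensionless): per-beat
#'     peak-minus-foot amplitudes of the two channels are put on a
#'     common scale by dividing by the larger of the two channels'
#'     median pulse amplitudes, so d4 is invariant to rescaling both
#'     channels jointly and equals `1 - ratio` for a pure amplitude
#'     ratio.}
#' }
#' Beats with missing landmarks are excluded from aggregation.
#'
#' @param windows_R,windows_L Beat tables for the right and left channel
#'   (see [segment_channel()]), needing columns `foot_time`,
#'   `peak_time`, `rise_time`, `amplitude`.
#' @return Named numeric vector `c(d1, d2, d3, d4)` (seconds, seconds,
#'   seconds, dimensionless), with attribute `n_beats` giving the number
#'   of matched beat pairs used.
#' @export
extract_features <- function(windows_R, windows_L) {
  if (nrow(windows_R) < 2 || nrow(windows_L) < 2)
    stop("need at least 2 beats per channel")
  pairs <- match_beats(windows_R$foot_time, windows_L$foot_time)
  if (nrow(pairs) < 2) stop("fewer than 2 matched beat pairs")
  R <- windows_R[pairs$r, ]
  L <- windows_L[pairs$l, ]
  amp_ref <- max(stats::median(R$amplitude), stats::median(L$amplitude))
  if (amp_ref <= 0) stop("non-positive pulse amplitudes")
  feats <- c(
    d1 = stats::median(abs(R$foot_time - L$foot_time)),
    d2 = stats::median(abs(R$peak_time - L$peak_time)),
    d3 = stats::median(abs(R$rise_time - L$rise_time)),
    d4 = stats::median(abs(R$amplitude - L$amplitude) / amp_ref)
  )
  attr(feats, "n_beats") <- nrow(pairs)
  feats
}

# Match beats across channels: for each right-channel foot, the nearest
# left-channel foot, accepted if within half the median beat period;
# duplicate left matches keep the closer beat.
match_beats <- function(feet_R, feet_L) {
  period <- stats::median(diff(sort(c(feet_R))))
  if (!is.finite(period)) period <- 0.8
  tol <- period / 2
  idx_l <- vapply(feet_R, function(fr) which.min(abs(feet_L - fr)), integer(1))
  dist <- abs(feet_L[idx_l] - feet_R)
  ok <- dist <= tol
  df <- data.frame(r = seq_along(feet_R)[ok], l = idx_l[ok], dist = dist[ok])
  if (nrow(df) == 0) return(df)
  # keep the closest right beat for each left beat
  df <- df[order(df$l, df$dist), ]
  df[!duplicated(df$l), c("r", "l")]
}

#' Compute the feature vector of a raw PPG record
#'
#' End-to-end per-subject path: Butterworth filtering, beat
#' segmentation on each channel, and [extract_features()].
#'
#' @param record A [ppg_record()].
#' @param ... Passed to [preprocess_record()].
#' @return Named feature vector `c(d1, d2, d3, d4)`.
#' @export
record_features <- function(record, ...) {
  seg <- preprocess_record(record, ...)
  extract_features(seg$right, seg$left)
}

#' Compute the feature table of a cohort
#'
#' @param cohort A `"ppg_cohort"` (see [generate_cohort()]) or any list
#'   of `list(record, meta)` pairs.
#' @param ... Passed to [record_features()].
#' @return Data.frame with columns `subject_id, d1, d2, d3, d4, dos,
#'   class`, one row per subject.
#' @export
cohort_features <- function(cohort, ...) {
  rows <- lapply(cohort, function(s) {
    f <- record_features(s$record, ...)
    data.frame(subject_id = s$meta$subject_id,
               d1 = f["d1"], d2 = f["d2"], d3 = f["d3"], d4 = f["d4"],
               dos = s$meta$dos, class = s$meta$true_class,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Min-max feature normalization
#'
#' Linear rescaling of each feature column to `[0, 1]` over the rows it
#' was fitted on: `x_hat = (x - min(x_k)) / (max(x_k) - min(x_k))`.
#' The scaler is fitted on training rows only and then applied to test
#' rows, which may therefore fall outside `[0, 1]`; values are never
#' clipped. Degenerate columns (`max == min`) are flagged at fit time
#' and map to 0 with a warning at apply time.
#'
#' @param features Numeric matrix or data.frame of raw feature rows
#'   (>= 2 rows).
#' @return `fit_minmax()` returns a list of class `"minmax_scaler"`
#'   with per-column `min` and `max`.
#' @examples
#' sc <- fit_minmax(cbind(a = c(0, 5, 10)))
#' apply_minmax(sc, cbind(a = c(0, 5, 10, 12)))
#' @export
fit_minmax <- function(features) {
  m <- as.matrix(features)
  if (nrow(m) < 2) stop("need at least 2 rows to fit a scaler")
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  if (any(maxs == mins))
    warning("degenerate feature column(s): max equals min")
  structure(list(min = mins, max = maxs), class = "minmax_scaler")
}

#' @param scaler A fitted `"minmax_scaler"`.
#' @rdname fit_minmax
#' @export
apply_minmax <- function(scaler, features) {
  p <- length(scaler$min)
  m <- if (is.null(dim(features))) {
    # a bare vector is one row when its length matches the scaler,
    # otherwise a single column
    if (length(features) == p && p > 1) matrix(features, nrow = 1)
    else matrix(features, ncol = 1)
  } else as.matrix(features)
  if (ncol(m) != p) stop("column count mismatch")
  rng <- scaler$max - scaler$min
  degen <- rng == 0
  if (any(degen)) {
    warning("degenerate column(s) mapped to 0")
    rng[degen] <- 1
  }
  out <- sweep(sweep(m, 2, scaler$min), 2, rng, "/")
  out[, degen] <- 0
  out
}

#' Write / read a feature table CSV
#'
#' Columns `subject_id, d1, d2, d3, d4, class` (plus any extras such as
#' `dos`), one row per subject; consumed by the classifier modules.
#'
#' @param features Feature table data.frame (see [cohort_features()]).
#' @param path CSV path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("d1", "d2", "d3", "d4")
  if (!all(need %in% names(df)))
    stop("feature CSV must contain columns d1..d4")
  df
}
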