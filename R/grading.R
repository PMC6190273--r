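#' Degree of stenosis from vessel diameters
#'
#' The degree of stenosis (DOS) quantifies the fractional narrowing of an
#' arteriovenous-fistula vessel from two B-mode ultrasound / angiography
#' measurements: `DOS = 1 - (d/D)^2`, where `d` is the stenosis lesion
#' diameter and `D` is the normal vessel diameter in the blood-flow
#' direction. A DOS of 1 (100\%) is total occlusion; a DOS of 0 means no
#' narrowing.
#'
#' @param d Stenosis lesion diameter (same length unit as `D`), `d >= 0`.
#' @param D Normal vessel diameter, strictly positive.
#' @return DOS as a fraction, vectorised over `d` and `D`. Values are in
#'   `[0, 1]` for physically plausible inputs (`0 <= d <= D`); `d > D`
#'   yields a negative DOS which is returned as-is with a warning, since
#'   it indicates an implausible measurement pair.
#' @examples
#' dos(1.52, 1.63)
#' dos(0, 1.0)     # total occlusion
#' @seealso [dos_to_class()] for the three-class partition.
#' @export
dos <- function(d, D) {
  if (any(!is.finite(d)) || any(!is.finite(D)))
    stop("diameters must be finite")
  if (any(D <= 0)) stop("normal vessel diameter D must be > 0")
  if (any(d < 0)) stop("lesion diameter d must be >= 0")
  out <- 1 - (d / D)^2
  if (any(out < 0))
    warning("d > D yields negative DOS; measurement pair implausible")
  out
}

#' Map a DOS fraction to a stenosis severity class
#'
#' Three clinically motivated severity bands: class 1 (mild,
#' `DOS <= 0.30`), class 2 (may impair hemodialysis efficiency,
#' `0.30 < DOS <= 0.50`), class 3 (surgical treatment usually required,
#' `DOS > 0.50`). Band edges are half-open with the boundary value
#' assigned to the lower class, so 0.30 is class 1 and 0.50 is class 2;
#' the edges can be moved via `breaks`.
#'
#' @param dos DOS fraction(s); finite. Negative values (implausible
#'   diameter pairs) map to class 1 with a warning.
#' @param breaks Two increasing cut points `c(low, high)` between the
#'   classes, default `c(0.30, 0.50)`.
#' @return Integer class labels in `{1, 2, 3}`.
#' @examples
#' dos_to_class(c(0.13, 0.45, 0.66))
#' @export
dos_to_class <- function(dos, breaks = c(0.30, 0.50)) {
  if (any(!is.finite(dos))) stop("dos must be finite")
  if (length(breaks) != 2L || breaks[1] >= breaks[2])
    stop("breaks must be two increasing cut points")
  if (any(dos < 0))
    warning("negative DOS mapped to class 1")
  ifelse(dos <= breaks[1], 1L, ifelse(dos <= breaks[2], 2L, 3L))
}

#' Build a subject metadata record
#'
#' Bundles the ultrasound diameters, DOS, demographics and severity class
#' of one subject. When `dos` is omitted it is computed from `d` and `D`;
#' when given, it is checked against the formula to 1e-6.
#'
#' @param subject_id Character id.
#' @param d,D Lesion and normal vessel diameters (see [dos()]).
#' @param dos_value Optional DOS fraction; defaults to `dos(d, D)`.
#' @param age Years.
#' @param gender `"male"` or `"female"`.
#' @param true_class Optional class in `{1,2,3}`; defaults to
#'   `dos_to_class(dos_value)`.
#' @return A list of class `"subject_meta"`.
#' @export
subject_meta <- function(subject_id, d, D, dos_value = NULL, age = NA_real_,
                         gender = NA_character_, true_class = NULL) {
  computed <- dos(d, D)
  if (is.null(dos_value)) {
    dos_value <- computed
  } else if (abs(dos_value - computed) > 1e-6) {
    warning(sprintf("recorded DOS %.6f disagrees with 1 - (d/D)^2 = %.6f",
                    dos_value, computed))
  }
  if (is.null(true_class)) true_class <- dos_to_class(dos_value)
  structure(list(subject_id = as.character(subject_id), d = d, D = D,
                 dos = dos_value, age = age, gender = gender,
                 true_class = as.integer(true_class)),
            class = "subject_meta")
}

#' @export
print.subject_meta <- function(x, ...) {
  cat(sprintf("Subject %s: d = %.3g, D = %.3g, DOS = %.1f%%, class %d\n",
              x$subject_id, x$d, x$D, 100 * x$dos, x$true_class))
  invisible(x)
}

#' Read or write a cohort manifest
#'
#' The manifest is a plain CSV with columns `subject_id, d, D, dos, age,
#' gender, class`, one row per subject.
#'
#' @param path CSV file path.
#' @return `read_manifest()` returns a data.frame; `write_manifest()`
#'   invisibly returns `path`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "d", "D", "dos", "age", "gender", "class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  df$class <- as.integer(df$class)
  df
}

#' @param manifest Data.frame with the manifest columns (see
#'   `read_manifest`).
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check a manifest's recorded DOS and class for internal consistency
#'
#' Clinical subject tables occasionally print DOS values that disagree
#' with their own diameter measurements, or class labels that disagree
#' with the DOS banding. This utility recomputes `1 - (d/D)^2` and
#' `dos_to_class()` for every row and reports the discrepancies instead
#' of silently trusting the recorded values.
#'
#' @param manifest Data.frame with columns `d`, `D`, `dos`, `class`.
#' @param tol Absolute tolerance on the DOS formula check (default 1e-4,
#'   i.e. agreement at the usual printed precision).
#' @return A data.frame with the recomputed `dos_formula`,
#'   `class_from_dos`, and logical flags `dos_consistent` (recorded DOS
#'   matches the formula), `class_consistent` (recorded class matches the
#'   band of the recorded DOS) and `plausible` (`d <= D`).
#' @export
dos_consistency_report <- function(manifest, tol = 1e-4) {
  stopifnot(all(c("d", "D", "dos", "class") %in% names(manifest)))
  formula_dos <- suppressWarnings(1 - (manifest$d / manifest$D)^2)
  cls <- suppressWarnings(dos_to_class(manifest$dos))
  data.frame(
    subject_id = if (!is.null(manifest$subject_id)) manifest$subject_id
                 else seq_len(nrow(manifest)),
    d = manifest$d, D = manifest$D,
    dos_recorded = manifest$dos,
    dos_formula = formula_dos,
    class_recorded = manifest$class,
    class_from_dos = cls,
    dos_consistent = abs(formula_dos - manifest$dos) <= tol,
    class_consistent = cls == manifest$class,
    plausible = manifest$d <= manifest$D,
    stringsAsFactors = FALSE
  )
}

#' Bundled 22-subject hemodialysis cohort table
#'
#' Diameter measurements (`d`, `D`), recorded DOS, age, gender and
#' severity class for a 22-patient hemodialysis cohort, as printed in the
#' clinical subject table this package's grading conventions follow. Many
#' rows are internally inconsistent (recorded DOS disagreeing with the
#' diameters, or class disagreeing with the DOS banding); use
#' [dos_consistency_report()] to enumerate them. Only rows whose recorded
#' DOS matches the formula should be treated as ground truth.
#'
#' @return The manifest data.frame.
#' @export
avf_subject_manifest <- function() {
  read_manifest(system.file("extdata", "avf_subjects.csv",
                            package = "avfppg", mustWork = TRUE))
}
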