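#' Confusion matrix for three-class predictions
#'
#' @param true,pred Equal-length class vectors with values in
#'   `{1, 2, 3}`; rows of the result are true classes, columns
#'   predictions.
#' @return A 3 x 3 integer matrix of class `"confusion_matrix"`.
#' @examples
#' confusion(c(1, 2, 3), c(1, 3, 3))
#' @export
confusion <- function(true, pred) {
  if (length(true) != length(pred)) stop("length mismatch")
  if (length(true) == 0) stop("empty input")
  true <- as.integer(true); pred <- as.integer(pred)
  if (!all(c(true, pred) %in% 1:3)) stop("labels must be in {1,2,3}")
  cm <- matrix(0L, 3, 3, dimnames = list(true = 1:3, predicted = 1:3))
  for (k in seq_along(true)) cm[true[k], pred[k]] <- cm[true[k], pred[k]] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest per class: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and precision (positive predictive value) `TP/(TP+FP)`;
#' macro values are unweighted means over the classes whose denominator
#' is defined (classes absent from both truth and prediction are
#' excluded with a warning). Accuracy is `trace/total`. All values are
#' percentages.
#'
#' @param cm A [confusion()] matrix.
#' @return A list of class `"metric_report"`: `accuracy`, `precision`,
#'   `specificity`, `sensitivity` (macro, \%), `per_class` data.frame,
#'   `n` and `cpu_time` (filled by callers that time training; purely
#'   informational).
#' @export
metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  per <- lapply(1:3, function(c) {
    TP <- cm[c, c]
    FN <- sum(cm[c, ]) - TP
    FP <- sum(cm[, c]) - TP
    TN <- total - TP - FN - FP
    data.frame(class = c,
               sensitivity = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
               specificity = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_,
               precision = if (TP + FP > 0) 100 * TP / (TP + FP) else NA_real_)
  })
  per <- do.call(rbind, per)
  absent <- rowSums(cm) == 0 & colSums(cm) == 0
  if (any(absent))
    warning("class(es) absent from truth and prediction excluded from macro means")
  macro <- function(v) mean(v[!absent], na.rm = TRUE)
  structure(list(accuracy = 100 * sum(diag(cm)) / total,
                 precision = macro(per$precision),
                 specificity = macro(per$specificity),
                 sensitivity = macro(per$sensitivity),
                 per_class = per, n = total, cpu_time = NA_real_,
                 confusion = cm),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "n = %d  accuracy %.2f%%  precision %.2f%%  specificity %.2f%%  sensitivity %.2f%%\n",
    x$n, x$accuracy, x$precision, x$specificity, x$sensitivity))
  if (is.finite(x$cpu_time)) cat(sprintf("training CPU time: %.2f s\n", x$cpu_time))
  invisible(x)
}

#' Train a stenosis classifier on a feature table
#'
#' Fits the min-max scaler on the given (training) rows, normalizes,
#' and trains either the ECOC one-vs-rest SVM or the MLP baseline. The
#' returned object bundles the scaler so that test subjects are
#' normalized with training statistics only.
#'
#' @param features Feature table with columns `d1..d4` and `class`
#'   (see [cohort_features()]).
#' @param classifier `"ecoc_svm"` or `"mlpn"`.
#' @param spec [kernel_spec()] for the SVM.
#' @param C Box constraint for the SVM.
#' @param seed Seed (MLP initialisation / SMO scan order).
#' @param ... Passed to [ecoc_fit()] or [mlpn_train()].
#' @return A list of class `"ppg_classifier"` with `scaler`, `model`,
#'   `classifier` and `cpu_time` (s).
#' @export
train_classifier <- function(features, classifier = c("ecoc_svm", "mlpn"),
                             spec = kernel_spec("quadratic"), C = 10,
                             seed = 1, ...) {
  classifier <- match.arg(classifier)
  Xraw <- as.matrix(features[, c("d1", "d2", "d3", "d4")])
  labels <- as.integer(features$class)
  scaler <- suppressWarnings(fit_minmax(Xraw))
  X <- suppressWarnings(apply_minmax(scaler, Xraw))
  t0 <- proc.time()[["elapsed"]]
  model <- if (classifier == "ecoc_svm") {
    ecoc_fit(X, labels, spec = spec, C = C, seed = seed, ...)
  } else {
    mlpn_train(X, labels, seed = seed, ...)
  }
  structure(list(scaler = scaler, model = model, classifier = classifier,
                 cpu_time = proc.time()[["elapsed"]] - t0),
            class = "ppg_classifier")
}

#' @param object,newdata,... A `"ppg_classifier"` and a feature table or
#'   raw feature matrix.
#' @rdname train_classifier
#' @export
predict.ppg_classifier <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) as.matrix(newdata[, c("d1", "d2", "d3", "d4")])
       else newdata
  Xs <- suppressWarnings(apply_minmax(object$scaler, X))
  as.integer(predict(object$model, Xs))
}

#' Cross-validated evaluation of a stenosis classifier
#'
#' Splits subjects into folds (leave-one-subject-out by default), fits
#' the normalization scaler and the classifier inside each training
#' fold only, predicts the held-out subjects, and pools all per-fold
#' predictions into a single confusion matrix. Folds whose training
#' part lacks one of the three classes are skipped with a warning.
#'
#' @param features Feature table with `d1..d4` and `class`.
#' @param classifier `"ecoc_svm"` or `"mlpn"`.
#' @param spec,C,seed,... Passed to [train_classifier()].
#' @param scheme `"loso"` (leave-one-subject-out) or `"kfold"`.
#' @param k Folds for `"kfold"`.
#' @return A [metrics()] report over the pooled predictions, with
#'   `predictions` (data.frame of subject, true, pred) attached.
#' @export
cross_validate <- function(features, classifier = "ecoc_svm",
                           spec = kernel_spec("quadratic"), C = 10,
                           scheme = c("loso", "kfold"), k = 5, seed = 1,
                           ...) {
  scheme <- match.arg(scheme)
  n <- nrow(features)
  if (min(table(factor(features$class, levels = 1:3))) < 2)
    stop("need at least 2 subjects per class")
  folds <- if (scheme == "loso") as.list(seq_len(n)) else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    split(sample.int(n), rep_len(seq_len(k), n))
  }
  true <- integer(0); pred <- integer(0); subj <- character(0)
  t0 <- proc.time()[["elapsed"]]
  for (fold in folds) {
    train <- features[-fold, , drop = FALSE]
    if (length(unique(train$class)) < 3) {
      warning("fold skipped: class missing from training part")
      next
    }
    clf <- train_classifier(train, classifier = classifier, spec = spec,
                            C = C, seed = seed, ...)
    p <- predict(clf, features[fold, , drop = FALSE])
    true <- c(true, features$class[fold])
    pred <- c(pred, p)
    subj <- c(subj, as.character(
      if (!is.null(features$subject_id)) features$subject_id[fold] else fold))
  }
  rep <- metrics(confusion(true, pred))
  rep$cpu_time <- proc.time()[["elapsed"]] - t0
  rep$predictions <- data.frame(subject_id = subj, true = true, pred = pred,
                                stringsAsFactors = FALSE)
  rep
}

#' SNR noise-robustness protocol
#'
#' Evaluates how a fixed clean-trained classifier degrades when
#' calibrated noise is added to the raw two-channel signals before
#' preprocessing. Mirroring the clinical protocol, the
#' evaluation set is restricted to the subjects the clean model
#' classifies 100\% correctly. For each SNR level and noise seed, both
#' channels of every selected record are corrupted with [add_noise()],
#' re-filtered, re-segmented and re-classified with the unchanged
#' model; metrics are averaged over seeds.
#'
#' @param cohort A `"ppg_cohort"` of clean records.
#' @param clf A trained `"ppg_classifier"` (clean data).
#' @param features Clean feature table of `cohort` (recomputed if
#'   omitted).
#' @param snr_list SNR levels in dB (default `c(40, 30, 20)`); `Inf`
#'   evaluates the clean signals.
#' @param n_seeds Noise realisations per SNR (default 10).
#' @param seed Master seed for the noise draws.
#' @param noise_type Noise construction (see [add_noise()]); the
#'   protocol defaults to `"surrogate"` — noise built from the raw PPG
#'   signal itself, spectrally matched so the target SNR is also the
#'   in-band SNR. `"white"` is available but is largely removed by the
#'   20 Hz front-end filter.
#' @param ... Passed to [record_features()].
#' @return A list of class `"noise_report"`: `summary` data.frame (one
#'   row per SNR: mean accuracy/precision/specificity/sensitivity over
#'   seeds), `per_seed` data.frame, and `selected` subject ids.
#' @export
noise_robustness <- function(cohort, clf, features = NULL,
                             snr_list = c(40, 30, 20), n_seeds = 10,
                             seed = 1,
                             noise_type = c("surrogate", "white"), ...) {
  noise_type <- match.arg(noise_type)
  if (is.null(features)) features <- cohort_features(cohort, ...)
  clean_pred <- predict(clf, features)
  sel <- which(clean_pred == features$class)
  if (length(sel) == 0) stop("no correctly classified clean subjects to corrupt")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  noise_seeds <- matrix(sample.int(.Machine$integer.max,
                                   n_seeds * length(sel) * length(snr_list)),
                        nrow = n_seeds)
  rows <- list()
  for (si in seq_along(snr_list)) {
    snr <- snr_list[si]
    for (rs in seq_len(n_seeds)) {
      true <- integer(0); pred <- integer(0)
      for (j in seq_along(sel)) {
        s <- cohort[[sel[j]]]
        ns <- noise_seeds[rs, (si - 1) * length(sel) + j]
        rec <- add_noise_record(s$record, snr, seed = ns %% 2147483000L,
                                type = noise_type)
        f <- tryCatch(record_features(rec, ...), error = function(e) NULL)
        if (is.null(f)) next  # segmentation failure counts as no pooled entry
        true <- c(true, s$meta$true_class)
        pred <- c(pred, predict(clf, matrix(f, nrow = 1)))
      }
      m <- suppressWarnings(metrics(confusion(true, pred)))
      rows[[length(rows) + 1L]] <- data.frame(
        snr_db = snr, seed_rep = rs, n = m$n, accuracy = m$accuracy,
        precision = m$precision, specificity = m$specificity,
        sensitivity = m$sensitivity)
    }
  }
  per_seed <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_seed, per_seed$snr_db), function(d) {
    data.frame(snr_db = d$snr_db[1], accuracy = mean(d$accuracy),
               precision = mean(d$precision),
               specificity = mean(d$specificity),
               sensitivity = mean(d$sensitivity))
  }))
  summ <- summ[order(-summ$snr_db), ]
  rownames(summ) <- NULL
  structure(list(summary = summ, per_seed = per_seed,
                 selected = features$subject_id[sel]),
            class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("Noise robustness over %d subjects, %d seeds per SNR:\n",
              length(x$selected), max(x$per_seed$seed_rep)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
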