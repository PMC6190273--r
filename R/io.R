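#' Save / load a trained classifier as JSON
#'
#' Serialises a `"ppg_classifier"` (min-max scaler plus either the ECOC
#' SVM ensemble — kernel spec, C, support vectors, multipliers, bias,
#' code matrix — or the MLP weight matrices) to a plain documented JSON
#' file.
#'
#' @param clf A `"ppg_classifier"` from [train_classifier()].
#' @param path JSON path.
#' @return `save_classifier_json()` invisibly returns `path`;
#'   `load_classifier_json()` returns the reconstructed classifier.
#' @export
save_classifier_json <- function(clf, path) {
  obj <- list(format = "avfppg-classifier", version = 1L,
              classifier = clf$classifier,
              scaler = list(min = unname(clf$scaler$min),
                            max = unname(clf$scaler$max)))
  if (clf$classifier == "ecoc_svm") {
    obj$code_matrix <- unname(unclass(clf$model$code_matrix))
    obj$C <- clf$model$C
    obj$kernel <- clf$model$kernel[c("family", "gamma", "rbf_form")]
    obj$models <- lapply(clf$model$models, function(m) list(
      support_vectors = unname(m$support_vectors),
      labels = m$labels, alphas = m$alphas, bias = m$bias))
  } else {
    obj$weights <- list(W1 = unname(clf$model$W1), b1 = clf$model$b1,
                        W2 = unname(clf$model$W2), b2 = clf$model$b2)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_classifier_json
#' @export
load_classifier_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "avfppg-classifier"))
    stop("not an avfppg classifier file")
  scaler <- structure(list(min = obj$scaler$min, max = obj$scaler$max),
                      class = "minmax_scaler")
  if (obj$classifier == "ecoc_svm") {
    spec <- kernel_spec(obj$kernel$family,
                        gamma = obj$kernel$gamma,
                        rbf_form = obj$kernel$rbf_form)
    models <- lapply(seq_len(length(obj$models)), function(k) {
      m <- if (is.data.frame(obj$models)) obj$models[k, ] else obj$models[[k]]
      structure(list(support_vectors = as.matrix(m$support_vectors),
                     labels = as.numeric(m$labels),
                     alphas = as.numeric(m$alphas),
                     bias = as.numeric(m$bias),
                     kernel = spec, C = obj$C,
                     converged = TRUE),
                class = "svm_model")
    })
    names(models) <- c("f1", "f2", "f3")
    model <- structure(list(code_matrix = ecoc_code_matrix(),
                            models = models, kernel = spec, C = obj$C),
                       class = "ecoc_svm")
  } else {
    model <- structure(list(W1 = as.matrix(obj$weights$W1),
                            b1 = as.numeric(obj$weights$b1),
                            W2 = as.matrix(obj$weights$W2),
                            b2 = as.numeric(obj$weights$b2)),
                       class = "mlpn_model")
  }
  structure(list(scaler = scaler, model = model,
                 classifier = obj$classifier, cpu_time = NA_real_),
            class = "ppg_classifier")
}
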