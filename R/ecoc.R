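#' The error-correcting output code matrix for three classes
#'
#' Each class is assigned a three-bit codeword — class 1: (1,1,1),
#' class 2: (0,1,0), class 3: (0,0,1) — and one binary learner is
#' trained per code column (f1, f2, f3): learner k's positive set is
#' the classes whose bit k is 1, so f1 separates class 1 from the rest,
#' f2 separates classes {1,2} from class 3, and f3 separates classes
#' {1,3} from class 2. Three learners respects the upper bound of
#' `2^(n-1) - 1` binary learners for `n = 3` classes.
#'
#' @return A 3 x 3 0/1 integer matrix, rows = classes, columns =
#'   learners.
#' @export
ecoc_code_matrix <- function() {
  m <- matrix(c(1L, 1L, 1L,
                0L, 1L, 0L,
                0L, 0L, 1L), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(class = 1:3, learner = c("f1", "f2", "f3"))
  m
}

#' Decode a binary output code against the class codewords
#'
#' Hard Hamming decoding: the predicted class minimises the Hamming
#' distance between the learners' output bits and the class codewords.
#' Hamming ties (possible, e.g. output (0,0,0) is at distance 1 from
#' both class 2 and class 3) are resolved by margin-weighted decoding —
#' minimising the sum of `|margin_k|` over mismatched bits, so bits the
#' learners were confident about cost more to flip — and any remaining
#' tie by the lowest class index.
#'
#' @param bits Integer/logical vector of output bits, one per learner.
#' @param margins Optional numeric vector of the learners' real-valued
#'   decision values (used only for tie-breaking).
#' @param code Code matrix (default [ecoc_code_matrix()]).
#' @return A list with `class`, `distances` (per-class Hamming
#'   distances) and `bits`.
#' @export
ecoc_decode <- function(bits, margins = NULL, code = ecoc_code_matrix()) {
  bits <- as.integer(bits)
  if (length(bits) != ncol(code)) stop("bit count mismatch")
  mism <- sweep(code, 2, bits, "!=")       # class x learner mismatches
  dist <- rowSums(mism)
  best <- which(dist == min(dist))
  if (length(best) > 1 && !is.null(margins)) {
    cost <- as.vector(mism[best, , drop = FALSE] %*% abs(margins))
    best <- best[cost == min(cost)]
  }
  list(class = as.integer(best[1]), distances = as.integer(dist),
       bits = bits)
}

#' Fit an ECOC one-versus-rest SVM ensemble
#'
#' Trains one binary soft-margin SVM per column of the code matrix,
#' relabelling the training classes by that column's bits (+1 for
#' classes with bit 1, -1 otherwise). All learners share the kernel and
#' box constraint.
#'
#' @param X Feature matrix, one row per subject.
#' @param labels Class labels in `{1, 2, 3}`; all three classes must be
#'   present.
#' @param spec A [kernel_spec()] (default quadratic, gamma 1).
#' @param C Box constraint (default 10).
#' @param ... Passed to [svm_train()].
#' @return A list of class `"ecoc_svm"` with `code_matrix` and `models`
#'   (list of three `"svm_model"`).
#' @export
ecoc_fit <- function(X, labels, spec = kernel_spec("quadratic"), C = 10, ...) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  code <- ecoc_code_matrix()
  if (!all(1:3 %in% labels))
    stop("all three classes must be present")
  models <- lapply(seq_len(ncol(code)), function(k) {
    y <- unname(ifelse(code[labels, k] == 1L, 1, -1))
    svm_train(X, y, spec = spec, C = C, ...)
  })
  names(models) <- colnames(code)
  structure(list(code_matrix = code, models = models,
                 kernel = models[[1]]$kernel, C = C),
            class = "ecoc_svm")
}

#' @export
print.ecoc_svm <- function(x, ...) {
  cat(sprintf("ECOC one-vs-rest SVM: 3 %s-kernel learners (C = %g)\n",
              x$kernel$family, x$C))
  invisible(x)
}

#' Classify with an ECOC SVM ensemble
#'
#' Each learner's decision value is thresholded at zero (`f_k >= 0`
#' maps to bit 1); the resulting output code is decoded with
#' [ecoc_decode()].
#'
#' @param ensemble A fitted `"ecoc_svm"`.
#' @param x A single feature vector.
#' @return For `ecoc_predict()`: a list with `class`, `output_code`,
#'   `distances` and `margins`. For the `predict` method: an integer
#'   vector of classes, one per row of `newdata`.
#' @export
ecoc_predict <- function(ensemble, x) {
  margins <- vapply(ensemble$models, function(m) svm_decision(m, x),
                    numeric(1))
  bits <- as.integer(margins >= 0)
  dec <- ecoc_decode(bits, margins, ensemble$code_matrix)
  list(class = dec$class, output_code = bits, distances = dec$distances,
       margins = margins)
}

#' @param object,newdata,... Standard predict-method arguments.
#' @rdname ecoc_predict
#' @export
predict.ecoc_svm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  M <- vapply(object$models, function(m) svm_decision(m, newdata),
              numeric(nrow(newdata)))
  M <- matrix(M, nrow = nrow(newdata))
  apply(M, 1, function(mg)
    ecoc_decode(as.integer(mg >= 0), mg, object$code_matrix)$class)
}
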