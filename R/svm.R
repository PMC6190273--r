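#' Kernel specification
#'
#' Kernels available to the SVM: `linear` (`x . z`), `quadratic`
#' (`(x . z + gamma)^2`, the pipeline's default) and `rbf`
#' (`exp(-gamma * ||x - z||^2)`). `rbf_form = "sum"` selects the
#' nonstandard variant `exp(-gamma * ||x + z||^2)` for fidelity
#' experiments; it is not a similarity kernel and is off by default.
#'
#' @param family `"quadratic"`, `"rbf"` or `"linear"`.
#' @param gamma Quadratic offset / RBF width. Defaults: 1 for
#'   quadratic; for RBF, `NULL` means `1 / n_features`, resolved at
#'   training time.
#' @param rbf_form `"difference"` (standard) or `"sum"`.
#' @return A list of class `"kernel_spec"`.
#' @export
kernel_spec <- function(family = c("quadratic", "rbf", "linear"),
                        gamma = NULL, rbf_form = c("difference", "sum")) {
  family <- match.arg(family)
  rbf_form <- match.arg(rbf_form)
  if (is.null(gamma) && family == "quadratic") gamma <- 1
  if (!is.null(gamma) && family == "rbf" && gamma <= 0)
    stop("rbf requires gamma > 0")
  structure(list(family = family, gamma = gamma, rbf_form = rbf_form),
            class = "kernel_spec")
}

# resolve a deferred RBF gamma against the feature dimension
resolve_gamma <- function(spec, n_features) {
  if (is.null(spec$gamma)) spec$gamma <- 1 / n_features
  spec
}

#' Evaluate a kernel
#'
#' `kernel_eval()` computes `K(x, z)` for two vectors; `kernel_matrix()`
#' computes the full Gram block between the rows of two matrices.
#'
#' @param spec A [kernel_spec()].
#' @param x,z Equal-length numeric vectors.
#' @return A scalar kernel value.
#' @examples
#' kernel_eval(kernel_spec("quadratic", gamma = 1), c(1, 0), c(1, 1))  # 4
#' @export
kernel_eval <- function(spec, x, z) {
  if (length(x) != length(z)) stop("dimension mismatch")
  drop(kernel_matrix(spec, matrix(x, nrow = 1), matrix(z, nrow = 1)))
}

#' @param X,Z Numeric matrices with one observation per row (same column
#'   count).
#' @return `kernel_matrix()` returns an `nrow(X) x nrow(Z)` matrix.
#' @rdname kernel_eval
#' @export
kernel_matrix <- function(spec, X, Z = X) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != ncol(Z)) stop("dimension mismatch")
  spec <- resolve_gamma(spec, ncol(X))
  switch(spec$family,
    linear = X %*% t(Z),
    quadratic = (X %*% t(Z) + spec$gamma)^2,
    rbf = {
      xx <- rowSums(X^2); zz <- rowSums(Z^2)
      cross <- X %*% t(Z)
      sq <- if (spec$rbf_form == "difference") {
        outer(xx, zz, "+") - 2 * cross
      } else {
        outer(xx, zz, "+") + 2 * cross
      }
      exp(-spec$gamma * pmax(sq, 0))
    },
    stop("unknown kernel family"))
}

#' Train a soft-margin kernel SVM (SMO)
#'
#' Solves the standard soft-margin dual
#' `max_alpha sum(alpha) - 0.5 * sum_ij alpha_i alpha_j y_i y_j K(x_i, x_j)`
#' subject to `0 <= alpha_i <= C` and `sum(alpha_i y_i) = 0`, by
#' sequential minimal optimization (pairwise working sets with the
#' max-|E1 - E2| second-choice heuristic). The decision function is
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b` with the bias averaged over
#' margin support vectors (`0 < alpha < C`). The returned model
#' satisfies the Karush-Kuhn-Tucker conditions within `tol`.
#'
#' @param X Numeric feature matrix, one row per observation.
#' @param y Labels in `{-1, +1}`; both classes must be present.
#' @param spec A [kernel_spec()].
#' @param C Box constraint, > 0 (default 10).
#' @param tol KKT tolerance (default 1e-3).
#' @param max_iter Hard cap on SMO update steps (default 10000).
#' @param seed Seed for the SMO scan-order randomisation (default 1;
#'   affects only the optimisation path, not the optimum).
#' @return A list of class `"svm_model"` with elements
#'   `support_vectors`, `labels`, `alphas`, `bias`, `kernel`, `C`,
#'   `n_iter` and `converged`.
#' @export
svm_train <- function(X, y, spec = kernel_spec("quadratic"), C = 10,
                      tol = 1e-3, max_iter = 10000, seed = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("label length mismatch")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (C <= 0) stop("C must be > 0")
  spec <- resolve_gamma(spec, ncol(X))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  K <- kernel_matrix(spec, X)
  alpha <- numeric(n)
  b <- 0
  # error cache: E_i = f(x_i) - y_i; with alpha = 0, f = b = 0
  E <- -y
  eps <- 1e-12
  n_iter <- 0L

  take_step <- function(i1, i2) {
    if (i1 == i2) return(FALSE)
    a1 <- alpha[i1]; a2 <- alpha[i2]
    y1 <- y[i1]; y2 <- y[i2]
    E1 <- E[i1]; E2 <- E[i2]
    s <- y1 * y2
    if (s > 0) { L <- max(0, a1 + a2 - C); H <- min(C, a1 + a2) }
    else { L <- max(0, a2 - a1); H <- min(C, C + a2 - a1) }
    if (L >= H - eps) return(FALSE)
    k11 <- K[i1, i1]; k12 <- K[i1, i2]; k22 <- K[i2, i2]
    eta <- k11 + k22 - 2 * k12
    if (eta > eps) {
      a2new <- a2 + y2 * (E1 - E2) / eta
      a2new <- min(max(a2new, L), H)
    } else {
      # eta <= 0 only for duplicate points (PSD kernel): the objective
      # is linear along the constraint line, so move to the bound the
      # gradient points at
      slope <- y2 * (E1 - E2)
      a2new <- if (slope > 1e-12) H else if (slope < -1e-12) L
               else return(FALSE)
    }
    if (abs(a2new - a2) < eps * (a2new + a2 + eps)) return(FALSE)
    a1new <- a1 + s * (a2 - a2new)
    # numerical guard
    if (a1new < 0) { a2new <- a2new + s * a1new; a1new <- 0 }
    if (a1new > C) { a2new <- a2new + s * (a1new - C); a1new <- C }
    # threshold update
    b1 <- b - E1 - y1 * (a1new - a1) * k11 - y2 * (a2new - a2) * k12
    b2 <- b - E2 - y1 * (a1new - a1) * k12 - y2 * (a2new - a2) * k22
    bnew <- if (a1new > eps && a1new < C - eps) b1
            else if (a2new > eps && a2new < C - eps) b2
            else (b1 + b2) / 2
    E <<- E + y1 * (a1new - a1) * K[, i1] + y2 * (a2new - a2) * K[, i2] +
      (bnew - b)
    alpha[i1] <<- a1new; alpha[i2] <<- a2new
    b <<- bnew
    n_iter <<- n_iter + 1L
    TRUE
  }

  examine <- function(i2) {
    y2 <- y[i2]; a2 <- alpha[i2]; E2 <- E[i2]
    r2 <- E2 * y2
    if (!((r2 < -tol && a2 < C) || (r2 > tol && a2 > 0))) return(FALSE)
    nb <- which(alpha > eps & alpha < C - eps)
    if (length(nb) > 1) {
      i1 <- nb[which.max(abs(E[nb] - E2))]
      if (take_step(i1, i2)) return(TRUE)
    }
    for (i1 in nb[sample.int(length(nb))]) if (take_step(i1, i2)) return(TRUE)
    for (i1 in sample.int(n)) if (take_step(i1, i2)) return(TRUE)
    FALSE
  }

  examine_all <- TRUE
  num_changed <- 0L
  while ((num_changed > 0L || examine_all) && n_iter < max_iter) {
    num_changed <- 0L
    idx <- if (examine_all) seq_len(n)
           else which(alpha > eps & alpha < C - eps)
    for (i2 in idx) {
      if (examine(i2)) num_changed <- num_changed + 1L
      if (n_iter >= max_iter) break
    }
    if (examine_all) examine_all <- FALSE
    else if (num_changed == 0L) examine_all <- TRUE
  }
  converged <- n_iter < max_iter

  # recompute the bias from margin support vectors for a clean estimate
  f0 <- drop(K %*% (alpha * y))
  Fb <- y - f0
  margin <- which(alpha > 1e-7 & alpha < C - 1e-7)
  b <- if (length(margin)) mean(Fb[margin]) else {
    # all alphas at bounds: KKT leaves an interval for b — lower bounds
    # b >= y_i - g_i from (y=+1, alpha<C) and (y=-1, alpha>0), upper
    # bounds from the mirror set; take the midpoint
    lower <- (y == 1 & alpha < C - 1e-7) | (y == -1 & alpha > 1e-7)
    upper <- (y == -1 & alpha < C - 1e-7) | (y == 1 & alpha > 1e-7)
    b_lo <- if (any(lower)) max(Fb[lower]) else -Inf
    b_hi <- if (any(upper)) min(Fb[upper]) else Inf
    if (is.finite(b_lo) && is.finite(b_hi)) (b_lo + b_hi) / 2
    else if (is.finite(b_lo)) b_lo
    else if (is.finite(b_hi)) b_hi else 0
  }

  sv <- which(alpha > 1e-8)
  structure(list(support_vectors = X[sv, , drop = FALSE],
                 labels = y[sv], alphas = alpha[sv], bias = b,
                 kernel = spec, C = C, n_iter = n_iter,
                 converged = converged,
                 alpha_full = alpha, X_train = X, y_train = y),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("SVM (%s kernel%s, C = %g): %d support vectors, bias %.4g%s\n",
              x$kernel$family,
              if (!is.null(x$kernel$gamma))
                sprintf(", gamma = %g", x$kernel$gamma) else "",
              x$C, length(x$alphas), x$bias,
              if (x$converged) "" else " [max_iter reached]"))
  invisible(x)
}

#' SVM decision values and sign predictions
#'
#' `svm_decision()` evaluates `f(x) = sum_i alpha_i y_i K(x_i, x) + b`
#' for each row of `X`; `predict.svm_model()` returns `sign(f)` (with
#' `f = 0` mapped to +1).
#'
#' @param model A trained `"svm_model"`.
#' @param X Matrix (or single vector) of query points.
#' @return Numeric decision values, one per query row.
#' @export
svm_decision <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Kq <- kernel_matrix(model$kernel, as.matrix(X), model$support_vectors)
  drop(Kq %*% (model$alphas * model$labels) + model$bias)
}

#' @param object,newdata,... Standard predict-method arguments.
#' @rdname svm_decision
#' @export
predict.svm_model <- function(object, newdata, ...) {
  f <- svm_decision(object, newdata)
  ifelse(f >= 0, 1, -1)
}

#' Check the KKT conditions of a trained SVM
#'
#' For each training point: `alpha = 0` requires `y f(x) >= 1 - tol`;
#' `0 < alpha < C` requires `|y f(x) - 1| <= tol`; `alpha = C` requires
#' `y f(x) <= 1 + tol`. Also checks `0 <= alpha <= C` and
#' `|sum(alpha y)|`.
#'
#' @param model A trained `"svm_model"` (with retained training data).
#' @param tol KKT tolerance.
#' @return List with `kkt_ok`, `max_violation`, `equality_gap`
#'   (`|sum alpha_i y_i|`) and `box_ok`.
#' @export
svm_kkt_check <- function(model, tol = 1e-3) {
  a <- model$alpha_full
  y <- model$y_train
  f <- svm_decision(model, model$X_train)
  m <- y * f
  viol <- numeric(length(a))
  free <- a > 1e-7 & a < model$C - 1e-7
  at0 <- a <= 1e-7
  atC <- a >= model$C - 1e-7
  viol[at0] <- pmax(0, 1 - m[at0])
  viol[free] <- abs(m[free] - 1)
  viol[atC] <- pmax(0, m[atC] - 1)
  list(kkt_ok = max(viol) <= tol,
       max_violation = max(viol),
       equality_gap = abs(sum(a * y)),
       box_ok = all(a >= -1e-9 & a <= model$C + 1e-9))
}

#' Small hyperparameter grid search
#'
#' Evaluates multiclass cross-validated accuracy over a grid of `C` and
#' `gamma` values and returns the grid sorted by accuracy. Utility for
#' choosing the empirically studied hyperparameters.
#'
#' @param features Feature table (see [cohort_features()]).
#' @param family Kernel family.
#' @param C_grid,gamma_grid Candidate values (default
#'   `c(0.1, 1, 10, 100)`).
#' @param k Folds for [cross_validate()] (default 5).
#' @param seed Fold seed.
#' @return Data.frame of grid points with pooled accuracy, best first.
#' @export
svm_grid_search <- function(features, family = "quadratic",
                            C_grid = c(0.1, 1, 10, 100),
                            gamma_grid = c(0.1, 1, 10, 100),
                            k = 5, seed = 1) {
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    rep <- cross_validate(features,
                          classifier = "ecoc_svm",
                          spec = kernel_spec(family, gamma = grid$gamma[i]),
                          C = grid$C[i], scheme = "kfold", k = k,
                          seed = seed)
    rep$accuracy
  }, numeric(1))
  grid$accuracy <- acc
  grid[order(-grid$accuracy), ]
}
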