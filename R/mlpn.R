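#' Multilayer perceptron baseline (log-sigmoid hidden layer, linear output)
#'
#' The comparison architecture for the ECOC-SVM: a single-hidden-layer
#' perceptron with 4 inputs, 36 log-sigmoid hidden units and 3 linear
#' outputs, trained on one-hot class targets by Levenberg-Marquardt
#' minimisation of the sum of squared errors. Prediction is the argmax
#' of the three linear outputs.
#'
#' `mlpn_init()` draws uniform weights in
#' `+/- sqrt(6 / (fan_in + fan_out))` under a fixed seed.
#'
#' @param input_dim,hidden_dim,output_dim Layer sizes (defaults 4, 36, 3).
#' @param seed Integer seed for the weight draw.
#' @return A list of class `"mlpn_model"` with `W1` (input x hidden),
#'   `b1`, `W2` (hidden x output), `b2`.
#' @export
mlpn_init <- function(input_dim = 4, hidden_dim = 36, output_dim = 3,
                      seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lim1 <- sqrt(6 / (input_dim + hidden_dim))
  lim2 <- sqrt(6 / (hidden_dim + output_dim))
  structure(list(
    W1 = matrix(stats::runif(input_dim * hidden_dim, -lim1, lim1),
                input_dim, hidden_dim),
    b1 = stats::runif(hidden_dim, -lim1, lim1),
    W2 = matrix(stats::runif(hidden_dim * output_dim, -lim2, lim2),
                hidden_dim, output_dim),
    b2 = stats::runif(output_dim, -lim2, lim2)),
    class = "mlpn_model")
}

logsig <- function(x) 1 / (1 + exp(-x))

#' Forward pass of the MLP
#'
#' @param model An `"mlpn_model"`.
#' @param X Feature matrix (or single vector) with `input_dim` columns.
#' @return An `nrow(X) x output_dim` matrix of linear output scores.
#' @export
mlpn_forward <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$W1)) stop("input dimension mismatch")
  H <- logsig(sweep(X %*% model$W1, 2, model$b1, "+"))
  sweep(H %*% model$W2, 2, model$b2, "+")
}

# pack / unpack the parameter vector (column-major, W1, b1, W2, b2)
mlpn_pack <- function(m) c(as.vector(m$W1), m$b1, as.vector(m$W2), m$b2)
mlpn_unpack <- function(theta, dims) {
  ni <- dims[1]; nh <- dims[2]; no <- dims[3]
  i1 <- ni * nh; i2 <- i1 + nh; i3 <- i2 + nh * no
  structure(list(W1 = matrix(theta[1:i1], ni, nh),
                 b1 = theta[(i1 + 1):i2],
                 W2 = matrix(theta[(i2 + 1):i3], nh, no),
                 b2 = theta[(i3 + 1):(i3 + no)]),
            class = "mlpn_model")
}

# residual vector r = vec(O - T) and its Jacobian dr/dtheta
# (rows ordered observation-fastest within each output unit)
mlpn_residual_jacobian <- function(theta, dims, X, Tgt, jacobian = TRUE) {
  ni <- dims[1]; nh <- dims[2]; no <- dims[3]
  m <- nrow(X)
  mod <- mlpn_unpack(theta, dims)
  A <- sweep(X %*% mod$W1, 2, mod$b1, "+")
  H <- logsig(A)
  O <- sweep(H %*% mod$W2, 2, mod$b2, "+")
  r <- as.vector(O - Tgt)
  if (!jacobian) return(list(r = r))
  Hp <- H * (1 - H)
  p <- length(theta)
  J <- matrix(0, m * no, p)
  i1 <- ni * nh; i2 <- i1 + nh; i3 <- i2 + nh * no
  for (k in seq_len(no)) {
    rows <- (k - 1) * m + seq_len(m)
    # hidden-layer weights: do_k/dW1[i,j] = W2[j,k] * H'_j * x_i
    G <- sweep(Hp, 2, mod$W2[, k], "*")        # m x nh
    for (j in seq_len(nh)) {
      cols <- (j - 1) * ni + seq_len(ni)
      J[rows, cols] <- X * G[, j]
    }
    J[rows, (i1 + 1):i2] <- G                   # hidden biases
    cols2 <- i2 + (k - 1) * nh + seq_len(nh)    # output weights, unit k
    J[rows, cols2] <- H
    J[rows, i3 + k] <- 1                        # output bias k
  }
  list(r = r, J = J)
}

#' Train the MLP by Levenberg-Marquardt
#'
#' Minimises the sum of squared errors between the linear outputs and
#' one-hot class targets. Each iteration solves
#' `(J'J + mu I) delta = -J'r`; steps that reduce the error are
#' accepted (`mu` divided by 10), others rejected (`mu` multiplied by
#' 10). Training stops when the gradient infinity-norm falls below
#' `grad_tol`, `mu` exceeds `mu_max`, or `max_epochs` accepted steps.
#' The accepted-step error sequence is non-increasing by construction.
#'
#' @param X Feature matrix (rows = subjects).
#' @param labels Class labels in `{1, 2, 3}` (one-hot encoded
#'   internally).
#' @param seed Weight-initialisation seed.
#' @param hidden_dim Hidden units (default 36).
#' @param max_epochs Maximum accepted LM steps (default 200).
#' @param mu0,mu_max LM damping start (1e-3) and ceiling (1e10).
#' @param grad_tol Gradient infinity-norm stopping tolerance (1e-7).
#' @return A trained `"mlpn_model"` with attributes `error_trace`
#'   (accepted-step SSE sequence) and `stop_reason`.
#' @export
mlpn_train <- function(X, labels, seed = 1, hidden_dim = 36,
                       max_epochs = 200, mu0 = 1e-3, mu_max = 1e10,
                       grad_tol = 1e-7) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite features")
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  no <- max(3L, length(classes))
  Tgt <- matrix(0, nrow(X), no)
  Tgt[cbind(seq_len(nrow(X)), labels)] <- 1
  dims <- c(ncol(X), hidden_dim, no)
  theta <- mlpn_pack(mlpn_init(ncol(X), hidden_dim, no, seed))

  mu <- mu0
  rj <- mlpn_residual_jacobian(theta, dims, X, Tgt)
  err <- sum(rj$r^2)
  trace <- err
  stop_reason <- "max_epochs"
  epoch <- 0L
  while (epoch < max_epochs) {
    g <- crossprod(rj$J, rj$r)
    if (max(abs(g)) < grad_tol) { stop_reason <- "gradient"; break }
    JtJ <- crossprod(rj$J)
    accepted <- FALSE
    while (!accepted) {
      delta <- tryCatch(
        solve(JtJ + diag(mu, ncol(JtJ)), -g),
        error = function(e) NULL)
      if (!is.null(delta)) {
        theta_new <- theta + as.vector(delta)
        r_new <- mlpn_residual_jacobian(theta_new, dims, X, Tgt,
                                        jacobian = FALSE)$r
        err_new <- sum(r_new^2)
        if (err_new < err) {
          theta <- theta_new
          err <- err_new
          mu <- mu / 10
          accepted <- TRUE
        } else mu <- mu * 10
      } else mu <- mu * 10
      if (mu > mu_max) break
    }
    if (!accepted) { stop_reason <- "mu_max"; break }
    epoch <- epoch + 1L
    trace <- c(trace, err)
    rj <- mlpn_residual_jacobian(theta, dims, X, Tgt)
  }
  model <- mlpn_unpack(theta, dims)
  attr(model, "error_trace") <- trace
  attr(model, "stop_reason") <- stop_reason
  attr(model, "epochs") <- epoch
  model
}

#' @export
print.mlpn_model <- function(x, ...) {
  cat(sprintf("MLP %d-%d-%d (log-sigmoid hidden, linear output)%s\n",
              nrow(x$W1), ncol(x$W1), ncol(x$W2),
              if (!is.null(attr(x, "epochs")))
                sprintf(", trained %d LM epochs (%s)", attr(x, "epochs"),
                        attr(x, "stop_reason")) else ""))
  invisible(x)
}

#' Predict classes with a trained MLP
#'
#' Argmax over the three linear outputs, ties to the lowest class index
#' (`which.max` semantics).
#'
#' @param model A trained `"mlpn_model"`.
#' @param X Feature matrix.
#' @return Integer class vector.
#' @export
mlpn_predict <- function(model, X) {
  O <- mlpn_forward(model, X)
  as.integer(apply(O, 1, which.max))
}

#' @param object,newdata,... Standard predict-method arguments.
#' @rdname mlpn_predict
#' @export
predict.mlpn_model <- function(object, newdata, ...) {
  mlpn_predict(object, newdata)
}

#' Multi-start MLP training
#'
#' Levenberg-Marquardt is a local optimiser: distinct seeds may reach
#' different optima. Trains `k` models from seeds derived from `seed`
#' and returns the one with the lowest final training error.
#'
#' @param X,labels,... As in [mlpn_train()].
#' @param k Number of starts (default 5).
#' @param seed Master seed.
#' @return The best `"mlpn_model"`; attribute `start_errors` holds all
#'   final errors.
#' @export
mlpn_train_multistart <- function(X, labels, k = 5, seed = 1, ...) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, k)
  fits <- lapply(seeds, function(s) mlpn_train(X, labels, seed = s, ...))
  errs <- vapply(fits, function(f) utils::tail(attr(f, "error_trace"), 1),
                 numeric(1))
  best <- fits[[which.min(errs)]]
  attr(best, "start_errors") <- errs
  best
}
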