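test_that("kernel evaluations match hand calculations", {
  expect_equal(kernel_eval(kernel_spec("quadratic", gamma = 1),
                           c(1, 0), c(1, 1)), 4)
  expect_equal(kernel_eval(kernel_spec("linear"), c(1, 2), c(3, 4)), 11)
  x <- rnorm(4)
  expect_equal(kernel_eval(kernel_spec("rbf", gamma = 0.7), x, x), 1)
  # the nonstandard sum-form RBF is selectable for fidelity experiments
  a <- c(1, 0); b <- c(0, 1)
  expect_equal(kernel_eval(kernel_spec("rbf", gamma = 0.5,
                                       rbf_form = "sum"), a, b),
               exp(-0.5 * sum((a + b)^2)))
  expect_error(kernel_eval(kernel_spec("linear"), 1:2, 1:3), "mismatch")
  expect_error(kernel_spec("rbf", gamma = -1), "gamma > 0")
})

test_that("Gram matrices are symmetric and positive semidefinite", {
  set.seed(4)
  X <- matrix(rnorm(80), 20, 4)
  for (spec in list(kernel_spec("linear"), kernel_spec("quadratic", gamma = 1),
                    kernel_spec("rbf", gamma = 0.5))) {
    K <- kernel_matrix(spec, X)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("two opposite points on a line recover the midpoint separator", {
  m <- svm_train(matrix(c(-1, 1), 2, 1), c(-1, 1), kernel_spec("linear"),
                 C = 10)
  expect_equal(svm_decision(m, matrix(-0.5)), -0.5, tolerance = 1e-6)
  expect_equal(svm_decision(m, matrix(0.5)), 0.5, tolerance = 1e-6)
  expect_equal(m$bias, 0, tolerance = 1e-6)
  # equal margins on the two training points
  f <- svm_decision(m, matrix(c(-1, 1), 2, 1))
  expect_equal(abs(f[1]), abs(f[2]), tolerance = 1e-6)
})

test_that("XOR is solved by the quadratic kernel", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(-1, -1, 1, 1)
  m <- svm_train(X, y, kernel_spec("quadratic", gamma = 1), C = 100)
  expect_identical(as.numeric(predict(m, X)), y)
  chk <- svm_kkt_check(m)
  expect_true(chk$kkt_ok)
})

test_that("trained models satisfy the dual feasibility invariants", {
  set.seed(10)
  X <- rbind(matrix(rnorm(40, -1), 20, 2), matrix(rnorm(40, 1), 20, 2))
  y <- rep(c(-1, 1), each = 20)
  for (spec in list(kernel_spec("linear"), kernel_spec("quadratic", gamma = 1),
                    kernel_spec("rbf", gamma = 0.5))) {
    for (C in c(0.1, 1, 10)) {
      m <- svm_train(X, y, spec, C = C)
      chk <- svm_kkt_check(m, tol = 1e-3)
      expect_true(chk$box_ok)
      expect_lt(chk$equality_gap, 1e-6)
      expect_true(chk$kkt_ok)
      expect_true(all(m$alphas > 0))  # only support vectors retained
    }
  }
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(svm_train(X, rep(1, 5)), "both classes")
  expect_error(svm_train(X, c(1, 1, -1, -1, 0)), "-1/\\+1")
  expect_error(svm_train(X, c(1, 1, 1, -1, -1), C = 0), "C must be")
})

test_that("duplicate training points do not break the optimiser", {
  X <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  y <- c(-1, -1, 1, 1)
  m <- svm_train(X, y, kernel_spec("linear"), C = 5)
  expect_identical(as.numeric(predict(m, X)), y)
  expect_true(svm_kkt_check(m)$kkt_ok)
})

test_that("decision values agree with an independent QP solver", {
  skip_if_not_installed("e1071")
  set.seed(21)
  X <- rbind(matrix(rnorm(60, -1.5), 30, 2), matrix(rnorm(60, 1.5), 30, 2))
  y <- rep(c(-1, 1), each = 30)
  cases <- list(
    list(spec = kernel_spec("linear"), ek = "linear", gamma = 1),
    list(spec = kernel_spec("rbf", gamma = 0.8), ek = "radial", gamma = 0.8))
  grid <- as.matrix(expand.grid(seq(-3, 3, 0.5), seq(-3, 3, 0.5)))
  for (cs in cases) {
    ours <- svm_train(X, y, cs$spec, C = 1)
    ref <- e1071::svm(X, factor(y), kernel = cs$ek, gamma = cs$gamma,
                      cost = 1, scale = FALSE)
    f_ours <- svm_decision(ours, grid)
    f_ref <- unname(attr(predict(ref, grid, decision.values = TRUE),
                         "decision.values")[, 1])
    # e1071 orients its decision value by first-seen class (-1 here)
    if (cor(f_ours, f_ref) < 0) f_ref <- -f_ref
    expect_gt(cor(f_ours, f_ref), 0.999)
    expect_lt(max(abs(f_ours - f_ref)), 0.02)
    expect_identical(f_ours >= 0, f_ref >= 0)
  }
})
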