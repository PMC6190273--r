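test_that("LOSO pools exactly one prediction per subject, deterministically", {
  feats <- small_features()
  rep1 <- cross_validate(feats, spec = kernel_spec("quadratic"), C = 10)
  expect_identical(rep1$n, nrow(feats))
  expect_identical(nrow(rep1$predictions), nrow(feats))
  rep2 <- cross_validate(feats, spec = kernel_spec("quadratic"), C = 10)
  expect_identical(rep1$predictions, rep2$predictions)
  expect_equal(rep1$accuracy, rep2$accuracy)
})

test_that("pooled LOSO accuracy is invariant to subject ordering", {
  feats <- small_features()
  set.seed(3)
  perm <- sample.int(nrow(feats))
  rep1 <- cross_validate(feats, spec = kernel_spec("quadratic"), C = 10)
  rep2 <- cross_validate(feats[perm, ], spec = kernel_spec("quadratic"),
                         C = 10)
  expect_equal(rep1$accuracy, rep2$accuracy)
})

test_that("k-fold scheme and the MLP baseline run through the same path", {
  feats <- small_features()
  repk <- cross_validate(feats, scheme = "kfold", k = 4, seed = 2)
  expect_identical(repk$n, nrow(feats))
  repm <- cross_validate(feats, classifier = "mlpn", scheme = "kfold",
                         k = 3, seed = 2, max_epochs = 40)
  expect_identical(repm$n, nrow(feats))
  expect_gte(repm$accuracy, 100 / 3)  # clearly better than chance floor
})

test_that("cross-validation demands two subjects per class", {
  feats <- small_features()
  expect_error(cross_validate(feats[feats$class != 2, ]), "2 subjects")
})

test_that("normalization is fitted inside the training fold only", {
  feats <- small_features()
  # an extreme held-out subject must not influence the training scaler:
  # train on all but the last row, whose d1 is made absurdly large
  feats2 <- feats
  feats2$d1[nrow(feats2)] <- 100
  clf_a <- train_classifier(feats[-nrow(feats), ])
  clf_b <- train_classifier(feats2[-nrow(feats2), ])
  expect_equal(clf_a$scaler$min, clf_b$scaler$min)
  expect_equal(clf_a$scaler$max, clf_b$scaler$max)
  # and test-fold values may leave [0, 1] unclipped
  x <- apply_minmax(clf_a$scaler,
                    as.matrix(feats2[nrow(feats2), c("d1", "d2", "d3", "d4")]))
  expect_gt(x[1], 1)
})

test_that("the clean sentinel reproduces clean metrics in the noise protocol", {
  coh <- small_cohort()
  feats <- small_features()
  clf <- train_classifier(feats)
  nr <- noise_robustness(coh, clf, feats, snr_list = c(Inf), n_seeds = 2,
                         seed = 1)
  # the evaluation set is the correctly classified clean subjects, and
  # Inf leaves the signals untouched, so clean metrics are all 100%
  expect_equal(nr$summary$accuracy, 100)
  expect_equal(nr$summary$sensitivity, 100)
  expect_identical(unique(nr$per_seed$n), length(nr$selected))
})

test_that("the noise protocol is reproducible and degrades with noise", {
  coh <- small_cohort()
  feats <- small_features()
  clf <- train_classifier(feats)
  nr1 <- noise_robustness(coh, clf, feats, snr_list = c(40, 15), n_seeds = 2,
                          seed = 5)
  nr2 <- noise_robustness(coh, clf, feats, snr_list = c(40, 15), n_seeds = 2,
                          seed = 5)
  expect_identical(nr1$per_seed, nr2$per_seed)
  expect_gte(nr1$summary$accuracy[1], nr1$summary$accuracy[2])
})

test_that("classifiers round-trip through JSON serialization", {
  feats <- small_features()
  Xq <- as.matrix(feats[, c("d1", "d2", "d3", "d4")])
  for (kind in c("ecoc_svm", "mlpn")) {
    clf <- if (kind == "mlpn")
      train_classifier(feats, classifier = kind, max_epochs = 30)
    else train_classifier(feats, classifier = kind)
    p <- withr::local_tempfile(fileext = ".json")
    save_classifier_json(clf, p)
    back <- load_classifier_json(p)
    expect_identical(predict(back, feats), predict(clf, feats))
    expect_equal(back$scaler$min, unname(clf$scaler$min))
  }
})

test_that("the hyperparameter grid search ranks by pooled accuracy", {
  feats <- blob_features(n_per_class = 5, seed = 3)
  grid <- svm_grid_search(feats, family = "quadratic", C_grid = c(1, 10),
                          gamma_grid = 1, k = 3, seed = 1)
  expect_identical(nrow(grid), 2L)
  expect_true(all(diff(grid$accuracy) <= 0))
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 100))
})
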