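test_that("bilateral difference pattern is |xR - xL| and symmetric", {
  expect_equal(as.numeric(bilateral_difference(c(3, 5, 2), c(1, 2, 4))),
               c(2, 3, 2))
  x <- rnorm(50)
  expect_equal(as.numeric(bilateral_difference(x, x)), rep(0, 50))
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(bilateral_difference(a, b), bilateral_difference(b, a))
  expect_true(all(bilateral_difference(a, b) >= 0))
  expect_error(bilateral_difference(1:3, 1:4), "lengths differ")
})

test_that("a pure foot delay appears in d1 and d2 only", {
  s <- generate_subject(dos = 0, seed = 3, duration = 10,
                        jitter = jitter_off(),
                        asymmetry = asymmetry_params(foot_delay = 0.050))
  f <- record_features(s$record)
  expect_equal(f[["d1"]], 0.050, tolerance = 0.005)
  expect_equal(f[["d2"]], 0.050, tolerance = 0.005)
  expect_lt(f[["d3"]], 0.005)
  expect_lt(f[["d4"]], 0.01)
})

test_that("a pure amplitude ratio appears in d4 only", {
  s <- generate_subject(dos = 0, seed = 3, duration = 10,
                        jitter = jitter_off(),
                        asymmetry = asymmetry_params(amplitude_ratio = 0.6))
  f <- record_features(s$record)
  expect_equal(f[["d4"]], 0.40, tolerance = 0.05)
  expect_lt(f[["d1"]], 0.002)
  expect_lt(f[["d2"]], 0.002)
  expect_lt(f[["d3"]], 0.002)
})

test_that("identical channels give features at the numerical floor", {
  s <- generate_subject(dos = 0, seed = 3, duration = 10,
                        jitter = jitter_off())
  f <- record_features(s$record)
  expect_lt(f[["d1"]], 0.002)
  expect_lt(f[["d2"]], 0.002)
  expect_lt(f[["d3"]], 0.002)
  expect_lt(f[["d4"]], 0.01)
})

test_that("features are invariant to joint rescaling and joint delay", {
  s <- generate_subject(dos = 0.5, seed = 13, duration = 10,
                        jitter = jitter_off())
  f0 <- record_features(s$record)
  # joint amplitude rescaling
  r_scaled <- s$record
  r_scaled$right <- 3.7 * r_scaled$right
  r_scaled$left <- 3.7 * r_scaled$left
  expect_lt(max(abs(record_features(r_scaled) - f0)), 1e-6)
  # joint time shift by k samples (boundary beats may enter/leave the
  # record, so the median aggregate can move by a fraction of a sample)
  k <- 250L
  r_shift <- s$record
  r_shift$right <- c(rep(s$record$right[1], k), s$record$right)
  r_shift$left <- c(rep(s$record$left[1], k), s$record$left)
  r_shift$duration <- length(r_shift$right) / r_shift$fs
  f_shift <- record_features(r_shift)
  expect_lt(max(abs(f_shift - f0)), 2e-3)
})

test_that("extract_features demands enough matched beats", {
  one_beat <- data.frame(foot_time = 1, peak_time = 1.15, rise_time = 0.15,
                         amplitude = 1)
  expect_error(extract_features(one_beat, one_beat), "at least 2")
  # non-overlapping channels: no matches within half a beat period
  bR <- data.frame(foot_time = c(1, 2), peak_time = c(1.2, 2.2),
                   rise_time = 0.2, amplitude = 1)
  bL <- data.frame(foot_time = c(10, 11), peak_time = c(10.2, 11.2),
                   rise_time = 0.2, amplitude = 1)
  expect_error(extract_features(bR, bL), "matched")
})

test_that("min-max scaler reproduces worked examples", {
  sc <- fit_minmax(cbind(x = c(0, 5, 10)))
  expect_equal(unname(sc$min), 0)
  expect_equal(unname(sc$max), 10)
  expect_equal(as.numeric(apply_minmax(sc, cbind(c(0, 5, 10)))), c(0, 0.5, 1))
  expect_equal(as.numeric(apply_minmax(sc, cbind(12))), 1.2)  # unclipped
  sc2 <- fit_minmax(cbind(c(2, 4)))
  expect_equal(as.numeric(apply_minmax(sc2, cbind(c(2, 4)))), c(0, 1))
})

test_that("min-max scaler handles degeneracy and mismatches", {
  expect_warning(sc <- fit_minmax(rbind(c(1, 2), c(1, 5))), "degenerate")
  expect_warning(out <- apply_minmax(sc, rbind(c(1, 3.5))), "degenerate")
  expect_equal(as.numeric(out), c(0, 0.5))
  expect_error(fit_minmax(rbind(c(1, 2))), "at least 2")
  sc3 <- fit_minmax(matrix(rnorm(20), 5, 4))
  expect_error(apply_minmax(sc3, matrix(1, 2, 3)), "mismatch")
})

test_that("scaling any matrix onto its own fit stays in [0, 1]", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(rnorm(60, sd = 10), 15, 4)
    out <- apply_minmax(fit_minmax(m), m)
    expect_true(all(out >= 0 & out <= 1))
    expect_equal(apply(out, 2, min), rep(0, 4), ignore_attr = TRUE)
    expect_equal(apply(out, 2, max), rep(1, 4), ignore_attr = TRUE)
  }
})

test_that("feature tables round-trip through CSV", {
  feats <- small_features()
  p <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(feats, p)
  back <- read_features_csv(p)
  expect_equal(back$d1, feats$d1, tolerance = 1e-12)
  expect_identical(back$class, feats$class)
})
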