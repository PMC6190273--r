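test_that("zero asymmetry with jitter off yields identical channels", {
  s <- generate_subject(dos = 0, seed = 7, duration = 10,
                        jitter = jitter_off())
  expect_lt(max(abs(s$record$right - s$record$left)), 1e-12)
})

test_that("zero DOS with jitter on keeps features below the jitter scale", {
  s <- generate_subject(dos = 0, seed = 7, duration = 10)
  f <- record_features(s$record)
  expect_lt(f[["d1"]], 0.02)   # landmark jitter is 5 ms SD per channel
  expect_lt(f[["d2"]], 0.02)
  expect_lt(f[["d3"]], 0.02)
  expect_lt(f[["d4"]], 0.10)
})

test_that("metadata diameters invert the DOS formula", {
  s <- generate_subject(dos = 1, seed = 2)
  expect_equal(s$meta$d, 0)
  expect_equal(s$meta$D, 1.0)
  s2 <- generate_subject(dos = 0.36, seed = 2)
  expect_equal(dos(s2$meta$d, s2$meta$D), 0.36, tolerance = 1e-12)
})

test_that("every raw feature is non-decreasing in DOS (jitter off)", {
  grid <- seq(0, 0.9, by = 0.1)
  feats <- t(vapply(grid, function(g) {
    s <- generate_subject(dos = g, seed = 3, duration = 10,
                          jitter = jitter_off())
    record_features(s$record)
  }, numeric(4)))
  for (j in 1:4) expect_true(all(diff(feats[, j]) >= -1e-6))
  # and strictly larger at dos 0.6 than at dos 0.2
  i2 <- which(grid == 0.2); i6 <- which(grid == 0.6)
  expect_true(all(feats[i6, ] > feats[i2, ]))
})

test_that("generate_subject validates its inputs", {
  expect_error(generate_subject(dos = -0.1), "\\[0, 1\\]")
  expect_error(generate_subject(dos = 1.1), "\\[0, 1\\]")
  expect_error(generate_subject(dos = 0.5, duration = 2), "five beat")
  expect_error(pulse_shape_params(notch_depth = 1.2), "between 0 and 1")
  expect_error(pulse_shape_params(rise_time = 0.5, notch_delay = 0.5),
               "beat period")
  expect_error(asymmetry_params(amplitude_ratio = 0), "amplitude_ratio")
})

test_that("cohorts have the contracted size, labels and determinism", {
  coh <- generate_cohort(3, seed = 9, duration = 5)
  expect_length(coh, 9L)
  man <- cohort_manifest(coh)
  expect_equal(unname(table(man$class)), rep(3L, 3), ignore_attr = TRUE)
  # class label always equals the banding of the drawn DOS
  expect_identical(man$class, unname(dos_to_class(man$dos)))
  # bitwise determinism
  coh2 <- generate_cohort(3, seed = 9, duration = 5)
  expect_identical(coh[[5]]$record$right, coh2[[5]]$record$right)
  expect_identical(cohort_manifest(coh2), man)
  # a different seed changes the waveforms
  coh3 <- generate_cohort(3, seed = 10, duration = 5)
  expect_false(identical(coh[[1]]$record$right, coh3[[1]]$record$right))
})

test_that("cohort generation rejects bad bands", {
  expect_error(generate_cohort(0), "n_per_class")
  expect_error(generate_cohort(2, class_dos_ranges = list(c(0, 1), c(0, 1))),
               "three")
  expect_error(generate_cohort(2, class_dos_ranges =
    list(c(0.3, 0.1), c(0.3, 0.5), c(0.5, 0.8))), "increasing")
})

test_that("additive noise hits the target SNR exactly by construction", {
  s <- generate_subject(dos = 0.3, seed = 4, duration = 10)
  for (type in c("white", "surrogate")) {
    for (snr in c(40, 30, 20)) {
      xn <- add_noise(s$record$right, snr, seed = 8, type = type)
      w <- xn - s$record$right
      emp <- 10 * log10(mean((s$record$right - mean(s$record$right))^2) /
                        mean(w^2))
      expect_equal(emp, snr, tolerance = 1e-6)
    }
  }
})

test_that("noise edge cases: clean sentinel, zero power, determinism", {
  x <- sin(seq(0, 20, by = 1e-3))
  expect_identical(add_noise(x, Inf, seed = 1), x)
  expect_error(add_noise(rep(0, 1000), 40), "zero power")
  expect_error(add_noise(x, NA), "finite")
  expect_identical(add_noise(x, 30, seed = 3), add_noise(x, 30, seed = 3))
  expect_false(identical(add_noise(x, 30, seed = 3), add_noise(x, 30, seed = 4)))
})

test_that("surrogate noise shares the signal's band, white noise does not", {
  s <- generate_subject(dos = 0.3, seed = 4, duration = 10)
  x <- s$record$right
  inband_power <- function(type) {
    xn <- add_noise(x, 20, seed = 11, type = type)
    w <- butterworth_lowpass(xn - x, zero_phase = TRUE)
    mean(w^2)
  }
  # the 20 Hz LPF keeps most surrogate noise but little white noise
  expect_gt(inband_power("surrogate") / inband_power("white"), 5)
})

test_that("PPG CSV round-trips with and without header", {
  s <- generate_subject(dos = 0.2, seed = 6, duration = 5)
  for (hdr in c(FALSE, TRUE)) {
    p <- withr::local_tempfile(fileext = ".csv")
    write_ppg_csv(s$record, p, header = hdr)
    back <- read_ppg_csv(p, fs = 1000)
    expect_equal(back$right, s$record$right, tolerance = 1e-12)
    expect_equal(back$left, s$record$left, tolerance = 1e-12)
  }
})
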