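test_that("preprocessing removes drift and common-mode activity", {
  n <- 2000
  t <- (seq_len(n) - 1) / fs_test
  common <- 30 * sin(2 * pi * 7 * t)
  x <- withr::with_seed(1, {
    arr <- array(rnorm(4 * 2 * n), dim = c(4, 2, n))
    arr + rep(common, each = 8) + 50   # common-mode + DC offset
  })
  out <- preprocess(x, fs_test)
  # channel mean ~ 0 at every sample
  expect_lt(max(abs(apply(out, c(2, 3), mean))), 1e-9)
  # DC gone
  expect_lt(abs(mean(out)), 0.1)
  # common-mode sinusoid removed
  p7 <- function(v) Mod(sum(v * exp(-2i * pi * 7 * t)))
  expect_lt(p7(out[1, 1, ]), p7(x[1, 1, ] - 50) / 100)
})

test_that("band envelopes track in-band amplitude", {
  n <- 3000
  t <- (seq_len(n) - 1) / fs_test
  x <- 3 * sin(2 * pi * 100 * t)
  env <- band_envelope(x, fs_test, "bgamma")
  core <- 500:2500
  expect_equal(mean(env[core]), 3, tolerance = 0.05 * 3)
  # out-of-band content is rejected
  y <- 3 * sin(2 * pi * 30 * t)
  expect_lt(mean(band_envelope(y, fs_test, "bgamma")[core]), 0.05)
  # linearity of the envelope under scaling
  expect_equal(band_envelope(2.5 * x, fs_test, "bgamma"), 2.5 * env,
               tolerance = 1e-9)
  # named bands resolve to their edges
  expect_equal(mparrm:::band_edges("theta"), c(4, 7))
  expect_error(mparrm:::band_edges("nope"), "unknown band")
})

test_that("baseline z-scoring centers trials and normalises variance", {
  bl <- 1:500
  p <- withr::with_seed(2, matrix(abs(rnorm(20 * 2000, mean = 5)), 20, 2000))
  z <- baseline_zscore(p, bl)
  expect_lt(max(abs(rowMeans(z[, bl]))), 1e-10)
  # white noise: post-baseline values ~ mean 0, sd 1
  expect_lt(abs(mean(z[, 501:2000])), 0.05)
  expect_equal(sd(z[, 501:2000]), 1, tolerance = 0.05)
  # scaling the input leaves z-units unchanged
  expect_equal(baseline_zscore(7 * p, bl), z, tolerance = 1e-10)
  expect_error(baseline_zscore(matrix(1, 3, 100), 1:10), "zero baseline")
})

test_that("bin_power partitions the 30 ms window into 5 ms bins", {
  arr <- array(2.5, dim = c(2, 3, 400))
  b <- bin_power(arr, 101, fs_test)
  expect_equal(nrow(b), 2 * 3 * 6)
  expect_true(all(b$power == 2.5))
  expect_equal(unique(b$t_hi_ms - b$t_lo_ms), 5)
  expect_equal(max(b$t_hi_ms), 30)
  # at 2 kHz each bin holds 10 samples: mark bin 3 only
  arr2 <- array(0, dim = c(1, 1, 400))
  arr2[1, 1, 101 + 20:29] <- 1
  b2 <- bin_power(arr2, 101, fs_test)
  expect_equal(b2$power, c(0, 0, 1, 0, 0, 0))
  expect_error(bin_power(arr, 390, fs_test), "out-of-range")
})

test_that("per-bin correlation behaves analytically", {
  n_obs <- 4000
  base <- withr::with_seed(3, {
    arr <- array(rnorm(n_obs * 60), dim = c(n_obs %/% 20, 20, 60))
  })
  bt <- bin_power(abs(base), 1, fs_test)
  expect_equal(pearson_by_bin(bt, bt)$r, rep(1, 6))
  # anti-correlated construction
  bt_neg <- dplyr::mutate(bt, power = -power)
  expect_equal(pearson_by_bin(bt_neg, bt)$r, rep(-1, 6))
  # adding independent noise of matched variance attenuates R towards 1/sqrt(2)
  noisy <- abs(base) + withr::with_seed(4, array(rnorm(length(base),
                                                       sd = sd(abs(base))),
                                                 dim = dim(base)))
  r <- pearson_by_bin(bin_power(noisy, 1, fs_test), bt,
                      level = "observation")$r
  expect_equal(mean(r), 1 / sqrt(2), tolerance = 0.06)
})

test_that("significance maps flag real effects at the nominal level", {
  n_tr <- 60
  arr <- withr::with_seed(5, array(rnorm(30 * n_tr * 60), dim = c(30, n_tr, 60)))
  arr[1:5, , ] <- arr[1:5, , ] + 1          # strong effect channels
  m <- significance_map(bin_power(arr, 1, fs_test))
  expect_true(all(m$significant[m$channel <= 5]))
  # null channels flag at about the test level
  null_rate <- mean(m$significant[m$channel > 5])
  expect_lt(null_rate, 0.05)
  expect_error(significance_map(bin_power(arr[, 1, , drop = FALSE], 1, fs_test)))
})

test_that("sensitivity and specificity follow the confusion table", {
  base <- tidyr::expand_grid(channel = 1:6, bin = 1)
  mt <- dplyr::mutate(base, significant = channel <= 3)
  expect_equal(unlist(sensitivity_specificity(mt, mt)[, c("sensitivity", "specificity")]),
               c(sensitivity = 1, specificity = 1))
  mc <- dplyr::mutate(mt, significant = !significant)
  expect_equal(unlist(sensitivity_specificity(mt, mc)[, c("sensitivity", "specificity")]),
               c(sensitivity = 0, specificity = 0))
  # hand-built case: truth = {1,2,3}, denoised = {1,4}
  md <- dplyr::mutate(base, significant = channel %in% c(1, 4))
  ss <- sensitivity_specificity(mt, md)
  expect_equal(ss$tp, 1); expect_equal(ss$fn, 2)
  expect_equal(ss$fp, 1); expect_equal(ss$tn, 2)
  expect_equal(ss$sensitivity, 1 / 3)
  expect_equal(ss$specificity, 2 / 3)
})

test_that("the fluctuation ratio contrasts artifact and baseline windows", {
  x <- withr::with_seed(6, rnorm(3400))
  expect_equal(fluctuation_ratio(x, 2001, fs_test), 1, tolerance = 0.6)
  y <- x; y[1999:2003] <- y[1999:2003] + c(-30, 40, -35, 20, -10)
  expect_gt(fluctuation_ratio(y, 2001, fs_test), 5)
  expect_error(fluctuation_ratio(rep(1, 3400), 2001, fs_test), "zero baseline")
})

test_that("spectral amplitude difference is a relative percentage", {
  a <- array(abs(withr::with_seed(7, rnorm(2 * 3 * 50))) + 1, dim = c(2, 3, 50))
  expect_true(all(spectral_amplitude_difference(a, a)$diff_pct == 0))
  d <- spectral_amplitude_difference(a, a * 1.1)
  expect_equal(d$diff_pct, rep(10, 50) * apply(a, 3, mean) / mean(a),
               tolerance = 1e-10)
  # three-sample hand computation
  h <- array(c(2, 4, 6), dim = c(1, 1, 3))
  hd <- array(c(3, 4, 5), dim = c(1, 1, 3))
  expect_equal(spectral_amplitude_difference(h, hd)$diff_pct,
               100 * c(1, 0, 1) / 4)
})

test_that("the interpolation baseline is the windowed straight line", {
  x <- withr::with_seed(8, array(rnorm(2 * 2 * 400), dim = c(2, 2, 400)))
  out <- interpolation_baseline(x, 200, fs_test)
  expect_equal(out[1, 2, ], interpolate_stim_window(x[1, 2, ], 200, fs_test))
  expect_equal(out[, , -(195:205)], x[, , -(195:205)])
})

test_that("ersp maps localise an injected burst", {
  n <- 1200
  t <- (seq_len(n) - 1) / fs_test
  burst <- 8 * exp(-pi * ((t - 0.45) / 0.05)^2) * sin(2 * pi * 100 * t)
  x <- withr::with_seed(9, matrix(rnorm(20 * n, sd = 2), 20, n))
  x_b <- sweep(x, 2, burst, "+")
  m0 <- ersp(x, fs_test, baseline_idx = 1:400)
  expect_lt(max(abs(m0$z[m0$time_s > 0.25])), 2.5)
  m1 <- ersp(x_b, fs_test, baseline_idx = 1:400)
  hot <- m1$z[m1$freq_hz > 80 & m1$freq_hz < 120 &
                abs(m1$time_s - 0.45) < 0.03]
  expect_gt(mean(hot), 3)
})

test_that("early-peak detection returns the first supra-threshold peak", {
  n <- 600
  expect_true(is.na(early_peak_time(rep(1, n), 300, fs_test, 1:200)))
  env2 <- withr::with_seed(10, rnorm(n, sd = 0.1) + 1)
  env2[324] <- env2[324] + 5 * sd(env2[1:200])   # +12 ms
  expect_equal(early_peak_time(env2, 300, fs_test, 1:200), 0.012)
  env2[380] <- env2[380] + 8 * sd(env2[1:200])   # later, larger peak
  expect_equal(early_peak_time(env2, 300, fs_test, 1:200), 0.012)
})
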