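test_that("the pulse grid enumerates every admissible charge-balanced shape", {
  g <- generate_pulse_grid()
  # brute-force enumeration with plain loops as the oracle
  count <- 0
  for (d1 in c(33, 66, 100, 200, 300))
    for (dp in c(0, 66, 100, 200, 300))
      for (d2 in c(33, 66, 100, 200, 300))
        if (d1 + dp + d2 <= 600) count <- count + 1
  expect_equal(nrow(g), count)
  expect_equal(nrow(g), 110)

  expect_true(all(g$d1_us + g$dp_us + g$d2_us <= 600))
  expect_equal(g$a2_ua, g$d1_us * g$a1_ua / g$d2_us)
  # charge balance d1*a1 = d2*a2 on every row
  expect_equal(g$d1_us * g$a1_ua, g$d2_us * g$a2_ua)
  expect_equal(g$a2_ua[g$d1_us == 100 & g$d2_us == 200 & g$dp_us == 100], 50)
  expect_false(any(g$d1_us == 300 & g$dp_us == 300 & g$d2_us == 300))
  # lexicographic (d1, dp, d2) order
  key <- g$d1_us * 1e6 + g$dp_us * 1e3 + g$d2_us
  expect_true(all(diff(key) > 0))
})

test_that("pulse waveforms are charge balanced on the sample grid", {
  g <- generate_pulse_grid()
  shape <- g[g$d1_us == 100 & g$dp_us == 100 & g$d2_us == 100, ]
  w <- pulse_waveform(shape, 30000)
  expect_equal(sum(w == -100), 3)   # 100 us at 30 kHz
  expect_equal(sum(w == 0), 3)
  # |integral| below the one-sample quantisation bound
  expect_lt(abs(sum(w) / 30000), max(abs(w)) / 30000 + 1e-12)

  nogap <- pulse_waveform(list(d1_us = 100, dp_us = 0, d2_us = 100,
                               a1_ua = 100, a2_ua = 100), 30000)
  expect_false(any(nogap == 0))
})

test_that("the synthetic artifact scales with injected charge", {
  peaks <- vapply(c(33, 100, 300), function(d1) {
    sh <- list(d1_us = d1, dp_us = 100, d2_us = 100, a1_ua = 100,
               a2_ua = d1 * 100 / 100)
    max(abs(synthesize_artifact(sh, fs_hz = 30000)$samples))
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))

  zero <- synthesize_artifact(list(d1_us = 100, dp_us = 100, d2_us = 100,
                                   a1_ua = 0, a2_ua = 0), fs_hz = 30000)
  expect_equal(max(abs(zero$samples)), 0)

  # energy concentrated shortly after onset
  ep <- synthesize_artifact(reference_pulse(), fs_hz = 30000)
  e <- ep$samples^2
  win <- seq(ep$onset_idx - 0.002 * 30000, ep$onset_idx + 0.012 * 30000)
  expect_gt(sum(e[win]) / sum(e), 0.99)
})

test_that("decimation preserves in-band content", {
  expect_error(decimate_signal(rnorm(100), 30000, 7000), "integer multiple")
  expect_equal(mparrm:::decimation_stages(15L), c(5L, 3L))

  # even-order Chebyshev anti-alias stages sit at the ripple floor at DC
  x <- rep(3, 3000)
  expect_equal(mean(decimate_signal(x, 30000, 2000)[10:190]), 3,
               tolerance = 0.025)

  t <- (0:29999) / 30000
  s <- sin(2 * pi * 100 * t)
  d <- decimate_signal(s, 30000, 2000)
  expect_equal(length(d), 2000)
  mid <- d[200:1800]
  # amplitude via RMS (a sampled peak under-reads at 20 samples/cycle)
  expect_equal(sd(mid) * sqrt(2), 1, tolerance = 0.015)
})

test_that("template averaging suppresses measurement noise", {
  sh <- reference_pulse()
  tm <- artifact_template(sh, n_trials = 60, seed = 3)
  tm2 <- artifact_template(sh, n_trials = 60, seed = 3)
  expect_identical(tm$samples, tm2$samples)   # deterministic under seed

  noiseless <- artifact_template(sh, n_trials = 1, noise_sd_uv = 0)
  expect_equal(max(abs(tm$samples)), max(abs(noiseless$samples)),
               tolerance = 0.05)

  # baseline noise shrinks ~ sqrt(n_trials)
  single <- artifact_template(sh, n_trials = 1, seed = 4)
  pre <- seq_len(tm$onset_idx - 20)
  expect_equal(sd(single$samples[pre]) / sd(tm$samples[pre]), sqrt(60),
               tolerance = 0.35)
})

test_that("ground-truth trials have the configured spectral slope", {
  p <- gt_params(line_amp_uv = 0, bursts_per_band = 0)
  x <- withr::with_seed(8, generate_ground_truth_trial(p, responsive = FALSE))
  n <- length(x)
  spec <- Mod(fft(x))^2 / n
  f <- seq_len(n / 2 - 1) * p$fs_hz / n
  keep <- f >= 2 & f <= 300
  fit <- lm(log(spec[2:(n / 2)][keep]) ~ log(f[keep]))
  expect_equal(unname(-coef(fit)[2]), p$bg_alpha, tolerance = 0.2)
})

test_that("responsive channels recover the injected effect size", {
  p <- gt_params()
  g <- 2
  n_tr <- 48
  z <- withr::with_seed(9, {
    trials <- t(vapply(seq_len(n_tr), function(i) {
      generate_ground_truth_trial(p, responsive = TRUE, effect_g = g)
    }, numeric(3400)))
    env <- band_envelope(trials, p$fs_hz, "bgamma")
    onset <- round(p$pre_s * p$fs_hz) + 1
    bl <- onset + seq(-0.5 * p$fs_hz, -0.1 * p$fs_hz)
    zz <- baseline_zscore(env, bl)
    plateau <- onset + seq(0.15 * p$fs_hz, 0.35 * p$fs_hz)
    mean(zz[, plateau])
  })
  expect_equal(z, g, tolerance = 0.35)

  z0 <- withr::with_seed(10, {
    trials <- t(vapply(seq_len(n_tr), function(i) {
      generate_ground_truth_trial(p, responsive = FALSE)
    }, numeric(3400)))
    env <- band_envelope(trials, p$fs_hz, "bgamma")
    onset <- round(p$pre_s * p$fs_hz) + 1
    bl <- onset + seq(-0.5 * p$fs_hz, -0.1 * p$fs_hz)
    mean(baseline_zscore(env, bl)[, onset:(onset + 0.4 * p$fs_hz)])
  })
  expect_lt(abs(z0), 0.3)
})

test_that("datasets decompose exactly into truth plus artifact", {
  ds <- assemble_dataset(n_channels = 3, n_trials = 4, seed = 21)
  diff <- ds$signals - ds$truth
  # identical artifact added to every trial of every channel
  for (ch in 1:3) for (tr in 1:4) {
    expect_equal(diff[ch, tr, ], ds$artifact, tolerance = 1e-12)
  }
  # zero outside the artifact support
  expect_equal(max(abs(diff[1, 1, 1:2500])), 0)

  ds2 <- assemble_dataset(n_channels = 3, n_trials = 4, seed = 21)
  expect_identical(ds$signals, ds2$signals)
  expect_identical(ds$responsive, ds2$responsive)

  ds3 <- assemble_dataset(n_channels = 3, n_trials = 4, seed = 22)
  expect_false(identical(ds$signals, ds3$signals))

  expect_error(assemble_dataset(responsive_frac = 1.5), "responsive_frac")
})

test_that("responsive fraction behaves binomially", {
  ds <- assemble_dataset(n_channels = 40, n_trials = 1, responsive_frac = 0.5,
                         seed = 30)
  expect_lt(abs(sum(ds$responsive) - 20), 4 * sqrt(40 * 0.25))
  expect_true(all(ds$effect_g[!ds$responsive] == 0))
  expect_true(all(ds$effect_g[ds$responsive] > 0))
})
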