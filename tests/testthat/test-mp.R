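test_that("a single dictionary atom is recovered exactly", {
  d <- test_dict(256)
  x <- 3 * atom_waveform(list(kind = "dirac", center_s = 20 / fs_test,
                              scale_s = 0, freq_hz = 0), 256, fs_test)
  dec <- mp_decompose(x, d, n_iter = 1)
  expect_equal(nrow(dec$atoms), 1)
  expect_equal(dec$atoms$kind, "dirac")
  expect_equal(dec$atoms$center_s, 20 / fs_test)
  expect_equal(dec$atoms$coeff, 3, tolerance = 1e-12)
  expect_equal(sum(dec$residual^2), 0, tolerance = 1e-20)
})

test_that("energy is conserved and the residual is non-increasing", {
  d <- test_dict(256)
  for (seed in 1:3) {
    x <- withr::with_seed(seed, rnorm(256))
    dec <- mp_decompose(x, d, n_iter = 50, stop_energy_frac = 0)
    e_in <- dec$input_energy
    expect_equal(e_in, sum(x^2))
    expect_lt(abs(e_in - sum(dec$atoms$energy) - sum(dec$residual^2)) / e_in,
              1e-6)
    # residual energy after k atoms is decreasing in k
    res_e <- e_in - cumsum(dec$atoms$energy)
    expect_true(all(diff(res_e) < 0))
    expect_true(all(res_e > -1e-9))
  }
})

test_that("each greedy selection matches a brute-force search", {
  cfg <- dictionary_config(n_freq = 6, anchor_freqs = c(60, 170))
  d <- test_dict(64, config = cfg)
  cand <- dict_candidates(d)
  x <- withr::with_seed(42, rnorm(64) + 5 * sin(2 * pi * 170 * (0:63) / fs_test))
  dec <- mp_decompose(x, d, n_iter = 3, stop_energy_frac = 0)
  r <- x
  for (k in 1:3) {
    best <- max(vapply(seq_len(nrow(cand)), function(j) {
      q <- r_quadrature(cand$kind[j], cand$center_s[j], cand$scale_s[j],
                        cand$freq_hz[j], 64, fs_test)
      r_proj_norm2(r, q)
    }, numeric(1)))
    expect_equal(dec$atoms$energy[k], best, tolerance = 1e-8)
    # replay the subtraction using the recorded atom
    keep <- seq_len(nrow(dec$atoms)) == k
    r <- r - reconstruct(dec, keep)
  }
})

test_that("decomposing two orthogonal atoms selects the larger first", {
  d <- test_dict(256)
  a1 <- atom_waveform(list(kind = "dirac", center_s = 0.02, scale_s = 0,
                           freq_hz = 0), 256, fs_test)
  a2 <- atom_waveform(list(kind = "dirac", center_s = 0.09, scale_s = 0,
                           freq_hz = 0), 256, fs_test)
  dec <- mp_decompose(5 * a1 + 2 * a2, d, n_iter = 2)
  expect_equal(abs(dec$atoms$coeff[1]), 5, tolerance = 1e-10)
  expect_equal(abs(dec$atoms$coeff[2]), 2, tolerance = 1e-10)
})

test_that("degenerate inputs are handled", {
  d <- test_dict(256)
  dec <- mp_decompose(numeric(256), d)
  expect_equal(nrow(dec$atoms), 0)
  expect_equal(sum(dec$residual^2), 0)
  expect_error(mp_decompose(c(NaN, numeric(255)), d), "invalid-input")
  expect_error(mp_decompose(numeric(100), d), "length")
  expect_error(mp_decompose(numeric(256), d, n_iter = 0), "n_iter")
})

test_that("reconstruction is linear and partitions exactly", {
  d <- test_dict(256)
  x <- withr::with_seed(3, rnorm(256, sd = 5))
  dec <- mp_decompose(x, d, n_iter = 20)
  expect_equal(reconstruct(dec, function(a) rep(FALSE, nrow(a))), numeric(256))
  full <- reconstruct(dec)
  expect_equal(full, x - dec$residual, tolerance = 1e-10)
  p <- dec$atoms$kind == "dirac"
  expect_equal(reconstruct(dec, p) + reconstruct(dec, !p), full,
               tolerance = 1e-12)
})

test_that("a criterion filter isolates a known component", {
  d <- test_dict(256)
  dir_w <- atom_waveform(list(kind = "dirac", center_s = 0.05, scale_s = 0,
                              freq_hz = 0), 256, fs_test)
  gab_w <- atom_waveform(list(kind = "gabor", center_s = 0.1, scale_s = 0.016,
                              freq_hz = 20, phase_rad = 0), 256, fs_test)
  dec <- mp_decompose(4 * dir_w + 7 * gab_w, d, n_iter = 2)
  only_dirac <- reconstruct(dec, dec$atoms$kind == "dirac")
  expect_equal(only_dirac, 4 * dir_w, tolerance = 1e-6)
})

test_that("line noise and a spike separate through criteria 1 and 3", {
  # epoch must exceed the 250 ms long-atom threshold for criterion 1
  d <- test_dict(512)
  t <- (0:511) / fs_test
  line <- 10 * sin(2 * pi * 60 * t + 1)
  spike <- numeric(512); spike[130] <- 50
  dec <- mp_decompose(line + spike, d, n_iter = 20)
  est_line <- reconstruct(dec, classify_atoms(dec$atoms, criterion = 1))
  est_spike <- reconstruct(dec, classify_atoms(dec$atoms, 129 / fs_test, 3))
  # cross-energy below 5%
  expect_lt(sum((est_line - line)^2) / sum(line^2), 0.05)
  expect_lt(sum((est_spike - spike)^2) / sum(spike^2), 0.05)
})

test_that("tidy and glance summarise a decomposition", {
  d <- test_dict(256)
  dec <- mp_decompose(withr::with_seed(1, rnorm(256)), d, n_iter = 10)
  td <- tidy(dec)
  expect_s3_class(td, "tbl_df")
  expect_false(any(startsWith(names(td), ".")))
  gl <- glance(dec)
  expect_equal(gl$n_atoms, 10)
  expect_gt(gl$explained_frac, 0)
  expect_lt(gl$explained_frac, 1)
})
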