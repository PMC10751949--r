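test_that("dictionary grids follow the dyadic/log-spaced construction", {
  d <- test_dict(256)
  # dyadic scales, enumerated independently
  dyadic <- 2^(1:8)
  expect_true(all(d$scale_grid %in% c(dyadic, 256L)))
  expect_true(max(d$scale_grid) == 256)
  # band-edge anchors are representable
  expect_true(all(c(55, 60, 70, 170) %in% d$freq_grid))
  expect_lt(max(d$freq_grid), fs_test / 2)
  # a 60 Hz Fourier candidate exists
  cand <- dict_candidates(d)
  expect_true(any(cand$kind == "fourier" & cand$freq_hz == 60))
})

test_that("invalid configurations are rejected", {
  expect_error(build_dictionary(2000, 4), "epoch_len")
  expect_error(build_dictionary(-1, 256), "fs_hz")
  expect_error(build_dictionary(2000, 256,
                                dictionary_config(kinds = character(0))))
})

test_that("every candidate waveform is unit norm", {
  d <- test_dict(64, config = dictionary_config(n_freq = 8))
  cand <- dict_candidates(d)
  idx <- round(seq(1, nrow(cand), length.out = 200))
  for (j in idx) {
    w <- mparrm:::mp_candidate_waveform_cpp(mparrm:::dict_engine(d), j)
    expect_equal(sum(w$u^2), 1, tolerance = 1e-9)
    if (w$hasv) expect_equal(sum(w$v^2), 1, tolerance = 1e-9)
  }
})

test_that("atom_waveform realises each family correctly", {
  # dirac: single nonzero entry
  w <- atom_waveform(list(kind = "dirac", center_s = 10 / fs_test,
                          scale_s = 0, freq_hz = 0), 32, fs_test)
  expect_equal(which(w != 0), 11)
  expect_equal(sum(w^2), 1, tolerance = 1e-12)

  # fourier: spectrum peaks at its frequency
  w <- atom_waveform(list(kind = "fourier", center_s = 0.5, scale_s = 1,
                          freq_hz = 60), 2000, fs_test)
  spec <- Mod(fft(w))[1:1000]
  expect_equal(which.max(spec), 61)  # bin 61 = 60 Hz at 1 Hz resolution

  # gabor approaches the fourier atom as the envelope flattens
  # (f * center integer so the two phase conventions coincide)
  f <- 125; ctr <- 0.064
  four <- atom_waveform(list(kind = "fourier", center_s = ctr, scale_s = 1,
                             freq_hz = f, phase_rad = 0), 256, fs_test)
  d_prev <- Inf
  for (s in c(0.1, 0.5, 4)) {
    gab <- atom_waveform(list(kind = "gabor", center_s = ctr, scale_s = s,
                              freq_hz = f, phase_rad = 0), 256, fs_test)
    d_now <- sqrt(sum((gab - four)^2))
    expect_lt(d_now, d_prev)
    d_prev <- d_now
  }
  expect_lt(d_prev, 0.05)

  expect_error(atom_waveform(list(kind = "dirac", center_s = 1, scale_s = 0,
                                  freq_hz = 0), 32, fs_test), "out-of-range")
})
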