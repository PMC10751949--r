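atom_row <- function(kind, center_s = 0.1, scale_s = 0.1, freq_hz = 0) {
  tibble::tibble(kind = kind, center_s = center_s, scale_s = scale_s,
                 freq_hz = freq_hz)
}

test_that("criterion 1 keeps long atoms above the line-noise floor", {
  expect_true(classify_atom(atom_row("fourier", scale_s = 0.256, freq_hz = 60),
                            criterion = 1))
  expect_false(classify_atom(atom_row("fourier", scale_s = 0.256, freq_hz = 40),
                             criterion = 1))
  # long but slow, and short but fast, both fail
  expect_false(classify_atom(atom_row("gabor", scale_s = 0.5, freq_hz = 10),
                             criterion = 1))
  expect_false(classify_atom(atom_row("gabor", scale_s = 0.01, freq_hz = 100),
                             criterion = 1))
})

test_that("criterion 2 keeps slow atoms only", {
  expect_true(classify_atom(atom_row("gabor", scale_s = 0.2, freq_hz = 10),
                            criterion = 2))
  expect_false(classify_atom(atom_row("gabor", scale_s = 0.2, freq_hz = 150),
                             criterion = 2))
  # sharp transients are never "below 70 Hz", whatever their nominal label
  expect_false(classify_atom(atom_row("dirac", scale_s = 0), criterion = 2))
  expect_false(classify_atom(atom_row("sharp_gaussian", scale_s = 0.004),
                             criterion = 2))
  # a long Gaussian envelope is slow
  expect_true(classify_atom(atom_row("sharp_gaussian", scale_s = 0.1),
                            criterion = 2))
})

test_that("criterion 3 keeps short high-frequency atoms near onset", {
  onset <- 0.1
  expect_true(classify_atom(atom_row("dirac", center_s = onset + 0.002,
                                     scale_s = 0), onset, 3))
  expect_false(classify_atom(atom_row("dirac", center_s = onset + 0.02,
                                      scale_s = 0), onset, 3))
  expect_true(classify_atom(atom_row("gabor", center_s = onset, scale_s = 0.004,
                                     freq_hz = 300), onset, 3))
  # too long a scale, or too far from onset, fails
  expect_false(classify_atom(atom_row("gabor", center_s = onset, scale_s = 0.016,
                                      freq_hz = 300), onset, 3))
  expect_false(classify_atom(atom_row("gabor", center_s = onset + 0.008,
                                      scale_s = 0.004, freq_hz = 300), onset, 3))
  # sharp gaussians within the window are artifact candidates
  expect_true(classify_atom(atom_row("sharp_gaussian", center_s = onset,
                                     scale_s = 0.008), onset, 3))
})

test_that("unknown criteria and missing onsets error", {
  expect_error(classify_atom(atom_row("dirac", scale_s = 0), criterion = 4),
               "invalid-config")
  expect_error(classify_atom(atom_row("dirac", scale_s = 0), criterion = 3),
               "onset")
})

test_that("thresholds are config-exposed", {
  rules <- criterion_rules(long_s = 0.05)
  expect_true(classify_atom(atom_row("gabor", scale_s = 0.06, freq_hz = 80),
                            criterion = 1, rules = rules))
  expect_false(classify_atom(atom_row("gabor", scale_s = 0.06, freq_hz = 80),
                             criterion = 1))
})
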