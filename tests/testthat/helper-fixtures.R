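# Shared fixtures: everything is generated in code at test time.

fs_test <- 2000

# small dictionary reused across tests (built once per test run)
test_dict <- local({
  cache <- NULL
  function(epoch_len = 256, fs = fs_test, config = dictionary_config()) {
    if (epoch_len == 256 && fs == fs_test && is.null(cache)) {
      cache <<- build_dictionary(fs, epoch_len, config)
    }
    if (epoch_len == 256 && fs == fs_test) return(cache)
    build_dictionary(fs, epoch_len, config)
  }
})

# unit-norm quadrature pair for a candidate row, built independently in R
# (mirrors the documented atom formulas, not the engine)
r_quadrature <- function(kind, center_s, scale_s, freq_hz, n, fs, trunc = 1.5) {
  t <- seq_len(n) - 1
  c_samp <- center_s * fs
  if (kind == "dirac") {
    u <- numeric(n); u[round(c_samp) + 1] <- 1
    return(list(u = u, v = NULL))
  }
  if (kind == "fourier") {
    th <- 2 * pi * freq_hz * t / fs
    u <- cos(th); v <- sin(th)
  } else {
    s_samp <- scale_s * fs
    env <- exp(-pi * ((t - c_samp) / s_samp)^2)
    env[abs(t - c_samp) > trunc * s_samp] <- 0
    if (kind == "sharp_gaussian") {
      u <- env; v <- NULL
    } else {
      th <- 2 * pi * freq_hz * (t - c_samp) / fs
      u <- env * cos(th); v <- env * sin(th)
    }
  }
  nu <- sqrt(sum(u^2))
  u <- u / nu
  if (!is.null(v)) {
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) v <- v / nv else v <- NULL
    if (!is.null(v) && 1 - sum(u * v)^2 < 1e-6) v <- NULL
  }
  list(u = u, v = v)
}

# phase-optimal squared projection norm of x onto the span of a candidate
r_proj_norm2 <- function(x, q) {
  if (is.null(q$v)) return(sum(q$u * x)^2)
  B <- cbind(q$u, q$v)
  drop(crossprod(qr.fitted(qr(B), x)))
}

# a saline-style denoising fixture: artifact + white noise, no neural signal
saline_fixture <- function(shape = generate_pulse_grid()[43, ], seed = 1) {
  saline_epoch(shape, seed = seed)
}

# short neural-like trial: pink-ish noise + optional 60 Hz line
neural_trial <- function(n = 512, fs = fs_test, line_uv = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- stats::filter(rnorm(n + 100, sd = 10), rep(1, 4) / 4, sides = 1)
    x <- as.numeric(x[101:(n + 100)])
    t <- (seq_len(n) - 1) / fs
    x + line_uv * sin(2 * pi * 60 * t + 1)
  })
}
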