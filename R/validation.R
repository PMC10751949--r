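#' Canonical frequency bands
#'
#' The six canonical bands used throughout the validation: theta 4-7,
#' alpha 8-12, low beta 13-20, high beta 20-30, low gamma 30-50 and
#' broadband gamma 70-170 Hz.
#'
#' @return Tibble with `band`, `lo_hz`, `hi_hz`.
#' @export
band_defs <- function() {
  tibble::tibble(
    band = c("theta", "alpha", "lbeta", "hbeta", "lgamma", "bgamma"),
    lo_hz = c(4, 8, 13, 20, 30, 70),
    hi_hz = c(7, 12, 20, 30, 50, 170))
}

band_edges <- function(band) {
  if (is.numeric(band) && length(band) == 2) return(band)
  bd <- band_defs()
  i <- match(band, bd$band)
  if (is.na(i)) stop("unknown band '", band, "'")
  c(bd$lo_hz[i], bd$hi_hz[i])
}

# apply FUN(vector) -> vector over the last dimension of a vector/matrix/
# 3-d array
apply_last_dim <- function(x, FUN) {
  if (is.null(dim(x))) return(FUN(x))
  d <- dim(x)
  if (length(d) == 2) {
    return(t(apply(x, 1, FUN)))
  }
  out <- x
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    out[i, j, ] <- FUN(x[i, j, ])
  }
  out
}

#' Preprocess multichannel signals
#'
#' Zero-phase 0.5 Hz Butterworth high-pass (slow-drift removal) followed
#' by a common-average-reference spatial filter (the across-channel mean
#' is subtracted at every sample).
#'
#' @param signals array `channels x trials x samples` (or matrix
#'   `channels x samples`).
#' @param fs_hz sampling rate (Hz).
#' @param hp_hz high-pass edge (Hz).
#' @return Array of the same shape.
#' @export
preprocess <- function(signals, fs_hz, hp_hz = 0.5) {
  bf <- signal::butter(2, hp_hz / (fs_hz / 2), type = "high")
  hp <- function(v) signal::filtfilt(bf, v)
  d <- dim(signals)
  if (is.null(d)) stop("invalid-input: preprocess expects a channels-first array")
  out <- apply_last_dim(signals, hp)
  if (length(d) == 2) {
    sweep(out, 2, colMeans(out))
  } else {
    m <- apply(out, c(2, 3), mean)   # trials x samples channel mean
    out - rep(m, each = d[1])
  }
}

# analytic signal via the FFT half-spectrum construction
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# zero-phase FIR band-pass design; transition band follows the common
# 3.3/tbw rule with tbw = max(lo / 4, 2) Hz, capped so filtfilt padding
# fits the epoch
band_fir <- function(fs, lo, hi, n_samples) {
  tbw <- max(lo / 4, 2)
  ord <- round(3.3 * fs / tbw)
  ord <- min(ord, floor((n_samples - 1) / 3))
  ord <- ord + ord %% 2   # even order -> symmetric type-I FIR
  signal::fir1(ord, c(lo, hi) / (fs / 2), type = "pass")
}

#' Band-power envelope
#'
#' Zero-phase (forward-backward) FIR band-pass followed by the magnitude
#' of the analytic signal.  Forward-backward filtering preserves the
#' temporal alignment with stimulation onset.
#'
#' @param x numeric vector, matrix or `channels x trials x samples` array.
#' @param fs_hz sampling rate (Hz).
#' @param band band name (see [band_defs()]) or `c(lo, hi)` in Hz.
#' @return Envelope, same shape as `x`.
#' @export
band_envelope <- function(x, fs_hz, band = "bgamma") {
  e <- band_edges(band)
  n <- if (is.null(dim(x))) length(x) else dim(x)[length(dim(x))]
  b <- band_fir(fs_hz, e[1], e[2], n)
  apply_last_dim(x, function(v) Mod(analytic_signal(signal::filtfilt(b, v))))
}

#' Baseline z-scoring of band power
#'
#' Normalises each trial by subtracting its own baseline-window mean and
#' dividing by the standard deviation of the (per-trial-centered) baseline
#' samples pooled across all trials of that channel.
#'
#' @param power array `channels x trials x samples` (or matrix
#'   `trials x samples` for one channel).
#' @param baseline_idx integer sample indices of the baseline window.
#' @return Same shape as `power`, in z-units; baseline mean is 0 per trial
#'   by construction.
#' @export
baseline_zscore <- function(power, baseline_idx) {
  z3 <- function(p) {   # trials x samples
    bl <- p[, baseline_idx, drop = FALSE]
    mu <- rowMeans(bl)
    p0 <- p - mu
    s <- sd(as.numeric(bl - mu))
    if (s == 0) stop("invalid-input: zero baseline variance")
    p0 / s
  }
  d <- dim(power)
  if (length(d) == 2) return(z3(power))
  out <- power
  for (ch in seq_len(d[1])) out[ch, , ] <- z3(power[ch, , ])
  out
}

#' Mean band power in 5 ms bins after stimulation onset
#'
#' Divides the window 0-30 ms after the artifact onset into six 5 ms bins
#' and averages the power samples within each bin, per channel and trial.
#'
#' @param power array `channels x trials x samples` (typically z-scored).
#' @param onset_idx artifact-onset sample (1-based; bin 1 starts at this
#'   sample).
#' @param fs_hz sampling rate (Hz).
#' @param bin_s bin width (s).
#' @param n_bins number of bins.
#' @return Tibble with `channel`, `trial`, `bin`, `t_lo_ms`, `t_hi_ms`,
#'   `power`.
#' @export
bin_power <- function(power, onset_idx, fs_hz, bin_s = 0.005, n_bins = 6) {
  d <- dim(power)
  stopifnot(length(d) == 3)
  bw <- round(bin_s * fs_hz)
  res <- purrr::map_dfr(seq_len(n_bins), function(b) {
    idx <- onset_idx + (b - 1) * bw + seq_len(bw) - 1
    if (max(idx) > d[3]) stop("out-of-range: bin window exceeds the epoch")
    m <- apply(power[, , idx, drop = FALSE], c(1, 2), mean)
    tibble::tibble(channel = rep(seq_len(d[1]), d[2]),
                   trial = rep(seq_len(d[2]), each = d[1]),
                   bin = b,
                   t_lo_ms = (b - 1) * bin_s * 1000,
                   t_hi_ms = b * bin_s * 1000,
                   power = as.numeric(m))
  })
  dplyr::arrange(res, .data$channel, .data$trial, .data$bin)
}

#' Per-bin Pearson correlation between denoised and ground-truth power
#'
#' Correlates the binned power of a denoised dataset against the ground
#' truth, separately per bin.  At the default `level = "channel"` the
#' correlation runs across channels on trial-averaged bin power -- the
#' quantity topographic response analyses use; `level = "observation"`
#' correlates the raw channel x trial values.
#'
#' @param denoised_bins,truth_bins [bin_power()] tibbles.
#' @param level `"channel"` (trial-averaged, default) or `"observation"`.
#' @return Tibble with `bin`, `t_lo_ms`, `t_hi_ms`, `r`, `n`.
#' @export
pearson_by_bin <- function(denoised_bins, truth_bins,
                           level = c("channel", "observation")) {
  level <- match.arg(level)
  j <- dplyr::inner_join(denoised_bins, truth_bins,
                         by = c("channel", "trial", "bin", "t_lo_ms", "t_hi_ms"),
                         suffix = c("_den", "_truth"))
  if (level == "channel") {
    j <- dplyr::summarise(
      dplyr::group_by(j, .data$channel, .data$bin, .data$t_lo_ms, .data$t_hi_ms),
      power_den = mean(.data$power_den),
      power_truth = mean(.data$power_truth), .groups = "drop")
  }
  dplyr::summarise(dplyr::group_by(j, .data$bin, .data$t_lo_ms, .data$t_hi_ms),
                   r = cor(.data$power_den, .data$power_truth),
                   n = dplyr::n(), .groups = "drop")
}

#' Per-channel, per-bin response significance map
#'
#' One-sample two-tailed t-test of the z-scored bin means across trials
#' against zero, per channel and bin.
#'
#' @param bins a [bin_power()] tibble of z-scored power.
#' @param alpha significance level (two-tailed), default 0.01.
#' @return Tibble with `channel`, `bin`, `t`, `p`, `significant`.
#' @export
significance_map <- function(bins, alpha = 0.01) {
  dplyr::summarise(
    dplyr::group_by(bins, .data$channel, .data$bin),
    t = {
      if (dplyr::n() < 2) stop("invalid-input: t-test needs >= 2 trials")
      unname(t.test(.data$power)$statistic)
    },
    p = t.test(.data$power)$p.value,
    .groups = "drop") |>
    dplyr::mutate(significant = .data$p < alpha)
}

#' Sensitivity and specificity of a denoised significance map
#'
#' Treats the ground-truth map as the reference: per bin,
#' `sensitivity = TP / (TP + FN)` and `specificity = TN / (TN + FP)` over
#' channels.
#'
#' @param map_truth,map_denoised [significance_map()] tibbles.
#' @return Tibble with `bin`, `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`.
#' @export
sensitivity_specificity <- function(map_truth, map_denoised) {
  j <- dplyr::inner_join(map_truth, map_denoised, by = c("channel", "bin"),
                         suffix = c("_truth", "_den"))
  dplyr::summarise(
    dplyr::group_by(j, .data$bin),
    tp = sum(.data$significant_truth & .data$significant_den),
    fn = sum(.data$significant_truth & !.data$significant_den),
    tn = sum(!.data$significant_truth & !.data$significant_den),
    fp = sum(!.data$significant_truth & .data$significant_den),
    .groups = "drop") |>
    dplyr::mutate(sensitivity = .data$tp / (.data$tp + .data$fn),
                  specificity = .data$tn / (.data$tn + .data$fp))
}

#' Signal fluctuation ratio around stimulation onset
#'
#' Standard deviation of the signal within the artifact window (default
#' 1 ms before to 1 ms after onset) divided by the standard deviation
#' within the baseline window (default 1000 ms to 200 ms before onset).
#' A ratio near 1 indicates complete artifact removal.
#'
#' @param signal numeric vector (one trial).
#' @param onset_idx stimulation-onset sample (1-based).
#' @param fs_hz sampling rate (Hz).
#' @param artifact_win_s,baseline_win_s windows in seconds relative to
#'   onset.
#' @return The fluctuation ratio (scalar).
#' @export
fluctuation_ratio <- function(signal, onset_idx, fs_hz,
                              artifact_win_s = c(-0.001, 0.001),
                              baseline_win_s = c(-1, -0.2)) {
  win <- function(w) {
    i <- onset_idx + seq.int(round(w[1] * fs_hz), round(w[2] * fs_hz))
    i <- i[i >= 1 & i <= length(signal)]
    if (length(i) < 2) stop("out-of-range: window outside the epoch")
    signal[i]
  }
  s_base <- sd(win(baseline_win_s))
  if (s_base == 0) stop("invalid-input: zero baseline standard deviation")
  sd(win(artifact_win_s)) / s_base
}

#' Spectral amplitude difference between denoised and ground truth
#'
#' Absolute temporal difference between the ground-truth and denoised
#' band envelopes, divided by the mean ground-truth amplitude, in percent,
#' averaged across channels and trials.
#'
#' @param truth_env,denoised_env arrays `channels x trials x samples`
#'   (band envelopes, same shape).
#' @param fs_hz sampling rate (Hz); used for the time axis.
#' @return Tibble with `sample`, `time_s`, `diff_pct`.
#' @export
spectral_amplitude_difference <- function(truth_env, denoised_env, fs_hz = NULL) {
  stopifnot(identical(dim(truth_env), dim(denoised_env)))
  d <- dim(truth_env)
  num <- apply(abs(truth_env - denoised_env), 3, mean)
  den <- mean(truth_env)
  tibble::tibble(sample = seq_len(d[3]),
                 time_s = if (is.null(fs_hz)) NA_real_ else (seq_len(d[3]) - 1) / fs_hz,
                 diff_pct = 100 * num / den)
}

#' Interpolation-based denoising baseline
#'
#' The conventional comparator: replaces the window around stimulation
#' onset by a straight line (same mechanics as
#' [interpolate_stim_window()]) and returns the result as the denoised
#' signal.  Samples outside the window are untouched.
#'
#' @param x numeric vector, matrix or `channels x trials x samples` array.
#' @param onset_idx stimulation-onset sample (1-based).
#' @param fs_hz sampling rate (Hz).
#' @param half_width_s interpolation half-width (s).
#' @return Same shape as `x`.
#' @export
interpolation_baseline <- function(x, onset_idx, fs_hz, half_width_s = 2.5e-3) {
  apply_last_dim(x, function(v) {
    interpolate_stim_window(v, onset_idx, fs_hz, half_width_s)
  })
}

#' Event-related spectral perturbation
#'
#' Time-frequency map of baseline z-scored band power around an event,
#' computed with a comb of narrow Hilbert bands and averaged across trials
#' (and channels, if a 3-d array is given).  Rendering-oriented; not part
#' of the quantitative metrics.
#'
#' @param x matrix `trials x samples` or array `channels x trials x
#'   samples`.
#' @param fs_hz sampling rate (Hz).
#' @param baseline_idx baseline sample indices for z-scoring.
#' @param freqs center frequencies (Hz) of the band comb.
#' @param bw_frac half-bandwidth of each comb band as a fraction of its
#'   center frequency.
#' @param decim temporal decimation factor of the output map.
#' @return Tibble with `time_s`, `freq_hz`, `z`.
#' @export
ersp <- function(x, fs_hz, baseline_idx,
                 freqs = c(seq(4, 28, 4), seq(34, 178, 8)),
                 bw_frac = 0.2, decim = 10) {
  if (length(dim(x)) == 3) {
    d <- dim(x)
    x <- matrix(aperm(x, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  }
  n <- ncol(x)
  keep <- seq(1, n, by = decim)
  purrr::map_dfr(freqs, function(f0) {
    lo <- max(f0 * (1 - bw_frac), 0.5)
    hi <- min(f0 * (1 + bw_frac), 0.495 * fs_hz)
    env <- band_envelope(x, fs_hz, c(lo, hi))
    z <- baseline_zscore(env, baseline_idx)
    tibble::tibble(time_s = (keep - 1) / fs_hz, freq_hz = f0,
                   z = colMeans(z)[keep])
  })
}

#' First early peak of the averaged broadband-gamma envelope
#'
#' Returns the time (s, relative to onset) of the first local maximum
#' after stimulation onset whose value exceeds the baseline mean by
#' `threshold_sd` baseline standard deviations; `NA` if no such peak
#' exists.
#'
#' @param avg_env numeric vector: trial-averaged broadband-gamma envelope.
#' @param onset_idx stimulation-onset sample (1-based).
#' @param fs_hz sampling rate (Hz).
#' @param baseline_idx baseline sample indices.
#' @param threshold_sd threshold in baseline SDs (default 3).
#' @return Peak time in seconds after onset, or `NA_real_`.
#' @export
early_peak_time <- function(avg_env, onset_idx, fs_hz, baseline_idx,
                            threshold_sd = 3) {
  thr <- mean(avg_env[baseline_idx]) + threshold_sd * sd(avg_env[baseline_idx])
  post <- seq.int(onset_idx + 1, length(avg_env) - 1)
  is_peak <- avg_env[post] > avg_env[post - 1] & avg_env[post] >= avg_env[post + 1]
  hit <- post[is_peak & avg_env[post] > thr]
  if (length(hit) == 0) return(NA_real_)
  (hit[1] - onset_idx) / fs_hz
}
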