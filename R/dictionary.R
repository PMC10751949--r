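#' Dictionary configuration
#'
#' Settings that control the over-complete matching-pursuit dictionary:
#' which atom families are enabled, the frequency grid, and the envelope
#' truncation used when atoms are realised on the sample grid.
#'
#' The dictionary combines four atom families:
#' * **Gabor** atoms (Gaussian envelope times a sinusoid) on a dyadic scale
#'   grid crossed with a log-spaced frequency grid, translated every
#'   `scale/4` samples;
#' * **sharp Gaussian** atoms (the shortest Gaussian envelopes, no
#'   oscillation), which capture fast non-oscillatory transients;
#' * **Dirac** atoms, one per sample position, which capture single-sample
#'   spikes;
#' * **Fourier** atoms (pure sinusoids spanning the whole epoch), which
#'   capture sustained periodic components such as line noise.
#'
#' @param kinds character vector of enabled atom families; subset of
#'   `c("gabor", "sharp_gaussian", "dirac", "fourier")`.
#' @param n_freq number of log-spaced frequency-grid points.
#' @param freq_min lower bound of the frequency grid (Hz).
#' @param freq_max_frac upper bound of the frequency grid as a fraction of
#'   the sampling rate (must stay below Nyquist, 0.5).
#' @param anchor_freqs frequencies (Hz) always inserted into the grid so
#'   that the classification band edges (55/70 Hz), line noise (60 Hz) and
#'   the broadband-gamma upper edge (170 Hz) are exactly representable.
#' @param scale_min smallest Gabor/Gaussian scale (samples).
#' @param gauss_max_s largest sharp-Gaussian scale (seconds); Gaussian atoms
#'   are restricted to the shortest scales because their role is to absorb
#'   fast transients.
#' @param trunc envelope truncation radius in units of the atom scale;
#'   truncated atoms are re-normalised to unit norm.
#' @param gabor_min_cycles Gabor cells with `freq_hz * scale_s` below this
#'   are excluded.  Atoms with less than half an oscillation cycle per
#'   envelope scale are unresolvable near-duplicates of the sharp-Gaussian
#'   family carrying a misleading nominal frequency (which would defeat
#'   the frequency-based classification criteria); between half a cycle
#'   and one cycle they are genuinely band-tuned transients -- the class
#'   that represents in-band artifact ringing -- and are kept.
#' @return A list of class `mp_dictionary_config`.
#' @export
dictionary_config <- function(kinds = c("gabor", "sharp_gaussian", "dirac", "fourier"),
                              n_freq = 48,
                              freq_min = 1,
                              freq_max_frac = 0.45,
                              anchor_freqs = c(55, 60, 70, 170),
                              scale_min = 2,
                              gauss_max_s = 0.01,
                              trunc = 1.5,
                              gabor_min_cycles = 0.5) {
  kinds <- match.arg(kinds, c("gabor", "sharp_gaussian", "dirac", "fourier"),
                     several.ok = TRUE)
  stopifnot(n_freq >= 2, freq_min > 0, freq_max_frac < 0.5, trunc > 0)
  structure(list(kinds = kinds, n_freq = n_freq, freq_min = freq_min,
                 freq_max_frac = freq_max_frac, anchor_freqs = anchor_freqs,
                 scale_min = scale_min, gauss_max_s = gauss_max_s,
                 trunc = trunc, gabor_min_cycles = gabor_min_cycles),
            class = "mp_dictionary_config")
}

kind_labels <- c("gabor", "sharp_gaussian", "dirac", "fourier")

#' Build a matching-pursuit dictionary
#'
#' Constructs the candidate atom set for a given epoch length and sampling
#' rate, together with a compiled engine that caches every candidate
#' waveform (truncated at `trunc` scales and re-normalised to unit norm).
#' Oscillatory candidates are handled as quadrature (cosine/sine) pairs, so
#' each `(kind, scale, frequency, center)` cell indexes one phase-optimal
#' unit-norm waveform.
#'
#' @param fs_hz sampling rate (Hz).
#' @param epoch_len epoch length in samples (>= 8).
#' @param config a [dictionary_config()].
#' @return An object of class `mp_dictionary` with the grids
#'   (`scale_grid` in samples, `freq_grid` in Hz), the enabled `kinds`, and
#'   the cached engine.
#' @examples
#' d <- build_dictionary(2000, 256)
#' d$scale_grid
#' @export
build_dictionary <- function(fs_hz, epoch_len, config = dictionary_config()) {
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("invalid-config: fs_hz must be > 0")
  if (!is.numeric(epoch_len) || epoch_len < 8) {
    stop("invalid-config: epoch_len must be at least 8 samples")
  }
  if (length(config$kinds) == 0) stop("invalid-config: no atom kinds enabled")
  epoch_len <- as.integer(epoch_len)

  scales <- 2^(seq.int(max(1, ceiling(log2(config$scale_min))),
                       floor(log2(epoch_len))))
  scales <- scales[scales >= config$scale_min]
  if (!epoch_len %in% scales) scales <- c(scales, epoch_len)

  fmax <- config$freq_max_frac * fs_hz
  freqs <- exp(seq(log(config$freq_min), log(fmax), length.out = config$n_freq))
  freqs <- sort(unique(c(freqs, config$anchor_freqs[config$anchor_freqs <= fmax])))

  gauss_scales <- scales[scales / fs_hz <= config$gauss_max_s]
  if (length(gauss_scales) == 0) gauss_scales <- scales[1]

  eng_env <- new.env(parent = emptyenv())
  dict <- structure(list(
    fs_hz = fs_hz, epoch_len = epoch_len,
    scale_grid = as.integer(scales), freq_grid = freqs,
    gauss_scales = as.integer(gauss_scales),
    kinds = config$kinds, config = config,
    eng = eng_env), class = "mp_dictionary")
  dict_engine(dict)  # build eagerly; cached in eng_env
  dict
}

# Engine accessor with lazy rebuild (external pointers do not survive
# serialisation; the environment lets a rebuilt pointer persist).
dict_engine <- function(dict) {
  ptr <- dict$eng$ptr
  if (!is.null(ptr) && mp_engine_valid(ptr)) return(ptr)
  k <- dict$kinds
  ptr <- mp_build_engine(
    n = dict$epoch_len, fs = dict$fs_hz,
    gabor_scales = if ("gabor" %in% k) dict$scale_grid else integer(0),
    gabor_freqs = dict$freq_grid,
    gauss_scales = if ("sharp_gaussian" %in% k) dict$gauss_scales else integer(0),
    fourier_freqs = if ("fourier" %in% k) dict$freq_grid else numeric(0),
    use_dirac = "dirac" %in% k,
    trunc = dict$config$trunc,
    gabor_min_cycles = dict$config$gabor_min_cycles %||% 0.5)
  dict$eng$ptr <- ptr
  dict$eng$info <- mp_engine_info(ptr)
  ptr
}

dict_info <- function(dict) {
  dict_engine(dict)
  dict$eng$info
}

#' Enumerate dictionary candidates
#'
#' Returns one row per candidate atom cell of the dictionary, in the
#' engine's internal (tie-break priority) order.
#'
#' @param dict an [build_dictionary()] result.
#' @return A tibble with `kind`, `center_s`, `scale_s`, `freq_hz`.
#' @export
dict_candidates <- function(dict) {
  info <- dict_info(dict)
  tibble::tibble(
    kind = kind_labels[info$kind + 1L],
    center_s = ifelse(info$kind == 3L, info$n / 2 / info$fs,
                      info$center / info$fs),
    scale_s = info$scale / info$fs,
    freq_hz = info$freq)
}

#' @export
print.mp_dictionary <- function(x, ...) {
  info <- dict_info(x)
  cat("<mp_dictionary> fs =", x$fs_hz, "Hz, epoch =", x$epoch_len, "samples\n")
  cat("  kinds:", paste(x$kinds, collapse = ", "), "\n")
  cat("  scales (samples):", paste(x$scale_grid, collapse = ", "), "\n")
  cat("  frequency grid:", length(x$freq_grid), "points in [",
      round(min(x$freq_grid), 2), ",", round(max(x$freq_grid), 2), "] Hz\n")
  cat("  candidates:", length(info$kind), "\n")
  invisible(x)
}

#' Realise an atom as a discrete waveform
#'
#' Generates the unit-norm waveform of a single atom on the sample grid.
#' Gabor atoms are a Gaussian envelope `exp(-pi ((t - c)/s)^2)` times
#' `cos(2 pi f (t - c) - phase)`; sharp Gaussians are the envelope alone;
#' a Dirac is 1 at its center sample; Fourier atoms are sinusoids spanning
#' the epoch.  Phase is measured relative to the atom center.  Atoms are
#' truncated at `trunc` scales from the center and re-normalised, matching
#' the dictionary engine exactly.
#'
#' @param atom a list or one-row data frame with `kind`, `center_s`,
#'   `scale_s`, `freq_hz`, `phase_rad` (missing phase defaults to 0).
#' @param epoch_len epoch length in samples.
#' @param fs_hz sampling rate (Hz).
#' @param trunc envelope truncation radius (units of scale).
#' @return Numeric vector of length `epoch_len` with unit L2 norm.
#' @export
atom_waveform <- function(atom, epoch_len, fs_hz, trunc = 1.5) {
  kind <- as.character(atom$kind)
  phase <- if (is.null(atom$phase_rad) || is.na(atom$phase_rad)) 0 else atom$phase_rad
  c_samp <- atom$center_s * fs_hz
  if (kind != "fourier" && (c_samp < 0 || c_samp > epoch_len - 1)) {
    stop("out-of-range: atom center outside epoch")
  }
  t <- seq_len(epoch_len) - 1
  w <- numeric(epoch_len)
  if (kind == "dirac") {
    w[round(c_samp) + 1] <- 1
  } else if (kind == "fourier") {
    w <- cos(2 * pi * atom$freq_hz * t / fs_hz - phase)
  } else {
    s_samp <- atom$scale_s * fs_hz
    if (s_samp <= 0) stop("invalid atom: non-dirac atom with zero scale")
    env <- exp(-pi * ((t - c_samp) / s_samp)^2)
    env[abs(t - c_samp) > trunc * s_samp] <- 0
    w <- if (kind == "gabor") {
      env * cos(2 * pi * atom$freq_hz * (t - c_samp) / fs_hz - phase)
    } else {
      env
    }
  }
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("invalid atom: zero waveform (over-truncated)")
  w / nrm
}
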