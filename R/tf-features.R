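#' Short-time power spectrum of a signal series
#'
#' Frames the series with a Hamming window (frame `t` covers samples
#' `[t*hop, t*hop + window_len)`, zero-based), takes the FFT per frame and
#' keeps the one-sided power spectrum on `[0, fs/2]`. Interior bins are
#' doubled so total one-sided power matches the two-sided spectrum. The number
#' of frames is `floor((len - window_len) / hop_len) + 1`.
#'
#' Each frame is detrended (its mean removed) by default: vectorized images
#' carry a large constant luminance offset that would otherwise concentrate
#' power at 0 Hz and mask the oscillatory content the features measure.
#'
#' @param series A [signal_series()].
#' @param window_len Window length in samples (even, >= 8; default 128). The
#'   FFT length equals the window length.
#' @param hop_len Hop between frame starts in samples (default `window_len/2`,
#'   i.e. 50\% overlap).
#' @param detrend Remove each frame's mean before windowing (default `TRUE`).
#' @return A `spectrogram` object: list with `P` (`T x F` power matrix),
#'   `times` (frame centres, s), `freqs` (bin centres, Hz, from 0 to `fs/2`),
#'   `fs`, `window_len`, `hop_len`.
#' @export
compute_spectrogram <- function(series, window_len = 128,
                                hop_len = window_len %/% 2, detrend = TRUE) {
  stopifnot(inherits(series, "signal_series"))
  x <- series$values
  n <- length(x)
  window_len <- as.integer(window_len)
  hop_len <- as.integer(hop_len)
  if (window_len < 8L) stop("window_len must be >= 8", call. = FALSE)
  if (window_len %% 2L != 0L) stop("window_len must be even", call. = FALSE)
  if (hop_len < 1L || hop_len > window_len) {
    stop("hop_len must be in [1, window_len]", call. = FALSE)
  }
  if (n < window_len) {
    stop("series of length ", n, " is shorter than the analysis window (",
         window_len, "); choose a smaller window_len", call. = FALSE)
  }
  n_frames <- (n - window_len) %/% hop_len + 1L
  starts <- (seq_len(n_frames) - 1L) * hop_len        # zero-based
  w <- as.numeric(signal::hamming(window_len))
  idx <- outer(seq_len(window_len), starts, `+`)      # window_len x T
  frames <- matrix(x[idx], nrow = window_len)
  if (detrend) frames <- sweep(frames, 2L, colMeans(frames))
  frames <- frames * w
  X <- stats::mvfft(frames)
  nb <- window_len %/% 2L + 1L                        # one-sided bins
  P <- Mod(X[seq_len(nb), , drop = FALSE])^2
  if (nb > 2L) P[2L:(nb - 1L), ] <- 2 * P[2L:(nb - 1L), ]
  structure(list(
    P = t(P),
    times = (starts + (window_len - 1) / 2) / series$fs,
    freqs = seq(0, series$fs / 2, length.out = nb),
    fs = series$fs, window_len = window_len, hop_len = hop_len
  ), class = "spectrogram")
}

# Floor near-zero power so per-frame normalization is always defined: an
# all-zero frame becomes uniform, giving IF = fs/4 and scaled SE = 1.
floor_power <- function(P) {
  pmax(P, .Machine$double.eps * max(max(P), 1))
}

#' Instantaneous frequency sequence
#'
#' The power-weighted mean frequency per frame:
#' `IF(t) = sum_m f_m P(t,m) / sum_m P(t,m)`. Frames with (near-)zero total
#' power are floored first, which makes their distribution uniform and their
#' IF equal to `fs/4`.
#'
#' @param spec A `spectrogram` from [compute_spectrogram()].
#' @return Numeric vector of length `T` (Hz), in `[0, fs/2]`.
#' @export
instantaneous_frequency <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  P <- floor_power(spec$P)
  as.vector(P %*% spec$freqs) / rowSums(P)
}

#' Spectral entropy sequence
#'
#' Shannon entropy of the per-frame normalized power spectrum
#' `p(t,m) = P(t,m) / sum_f P(t,f)`:
#' `SE(t) = -sum_m p(t,m) log2 p(t,m)`, with `0 log2 0 = 0`. When
#' `scaled = TRUE` (default) the entropy is divided by `log2(F)` so a flat
#' spectrum scores 1 and a pure tone scores near 0.
#'
#' @param spec A `spectrogram`.
#' @param scaled Divide by `log2(F)`? Default `TRUE`.
#' @return Numeric vector of length `T`.
#' @export
spectral_entropy <- function(spec, scaled = TRUE) {
  stopifnot(inherits(spec, "spectrogram"))
  P <- floor_power(spec$P)
  p <- P / rowSums(P)
  se <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  if (scaled) se <- se / log2(ncol(P))
  se
}

#' Time-frequency feature sequence (IF and SE)
#'
#' Computes one spectrogram and derives instantaneous frequency and spectral
#' entropy from it, so both sequences share the same frames and length.
#'
#' @inheritParams compute_spectrogram
#' @param scaled Scale SE to `[0, 1]`? Default `TRUE`.
#' @return A `tf_sequence` object: list with `if_hz`, `se`, `times`, `fs` and
#'   the underlying `spectrogram`.
#' @export
tf_sequence <- function(series, window_len = 128,
                        hop_len = window_len %/% 2, scaled = TRUE,
                        detrend = TRUE) {
  spec <- compute_spectrogram(series, window_len, hop_len, detrend = detrend)
  structure(list(
    if_hz = instantaneous_frequency(spec),
    se = spectral_entropy(spec, scaled = scaled),
    times = spec$times, fs = spec$fs, spectrogram = spec
  ), class = "tf_sequence")
}

#' @export
print.tf_sequence <- function(x, ...) {
  cat("time-frequency sequence: ", length(x$if_hz), " frames, fs = ", x$fs,
      " Hz\n  IF [Hz]: ", sep = "")
  cat(sprintf("%.2f", stats::quantile(x$if_hz, c(0, .5, 1))), sep = " / ")
  cat("  (min/median/max)\n  SE: ")
  cat(sprintf("%.3f", stats::quantile(x$se, c(0, .5, 1))), sep = " / ")
  cat("\n")
  invisible(x)
}

#' Write a time-frequency sequence to CSV
#'
#' Columns: `frame`, `time_s`, `if_hz`, `se`.
#'
#' @param tf A `tf_sequence`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tf_csv <- function(tf, path) {
  utils::write.csv(data.frame(frame = seq_along(tf$if_hz), time_s = tf$times,
                              if_hz = tf$if_hz, se = tf$se),
                   path, row.names = FALSE)
  invisible(path)
}
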