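# Mel-frequency cepstral coefficients: the short-term feature whose
# frame-level trajectories feed the modulation spectrum.

#' Acoustic feature settings
#'
#' Frame, filterbank and modulation-analysis settings used throughout the
#' acoustic pipeline. Defaults are conventional for 16 kHz speech:
#' 25 ms Hamming frames at a 10 ms hop (100 frames/s), a 26-filter mel
#' filterbank up to Nyquist, 13 cepstra including c0, and a 512-point
#' temporal DFT for the modulation spectrum (~0.195 Hz bin spacing).
#'
#' @param frame_len_s Analysis frame length in seconds.
#' @param hop_s Frame hop in seconds; the MFCC frame rate is `1/hop_s` Hz.
#' @param n_mels Number of triangular mel filters.
#' @param n_mfcc Number of cepstral coefficients kept (including c0).
#' @param preemphasis First-order pre-emphasis coefficient (0 disables).
#' @param mod_n_fft Analysis length (frames) for the temporal DFT of each
#'   coefficient trajectory; shorter utterances are zero-padded so
#'   modulation bins align across utterances.
#' @param n_components Number of lower-order (lowest-frequency, non-DC)
#'   modulation components extracted as classifier features.
#' @param log_floor Floor applied inside logs to keep values finite.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(frame_len_s = 0.025, hop_s = 0.010,
                           n_mels = 26L, n_mfcc = 13L,
                           preemphasis = 0.97,
                           mod_n_fft = 512L, n_components = 20L,
                           log_floor = 1e-12) {
  if (frame_len_s < hop_s) vs_invalid("frame_len_s must be >= hop_s")
  if (hop_s <= 0) vs_invalid("hop_s must be positive")
  if (!is_count(n_mels) || n_mels < 2) vs_invalid("n_mels must be >= 2")
  if (!is_count(n_mfcc) || n_mfcc < 1 || n_mfcc > n_mels)
    vs_invalid("n_mfcc must be in 1..n_mels")
  if (!is_count(mod_n_fft) || mod_n_fft < 8)
    vs_invalid("mod_n_fft must be an integer >= 8")
  structure(list(frame_len_s = frame_len_s, hop_s = hop_s,
                 n_mels = as.integer(n_mels), n_mfcc = as.integer(n_mfcc),
                 preemphasis = preemphasis,
                 mod_n_fft = as.integer(mod_n_fft),
                 n_components = as.integer(n_components),
                 log_floor = log_floor),
            class = "feature_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank, n_mels x n_bins, spanning 0 .. sr/2.
mel_filterbank <- function(n_mels, n_fft, sr) {
  n_bins <- n_fft %/% 2L + 1L
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(sr / 2), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freqs <- (0:(n_bins - 1L)) * sr / n_fft
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (bin_freqs - lo) / (ce - lo)
    dn <- (hi - bin_freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

# Orthonormal DCT-II matrix, n_out x n_in.
dct_matrix <- function(n_out, n_in) {
  k <- 0:(n_out - 1L)
  n <- 0:(n_in - 1L)
  D <- cos(outer(k, (n + 0.5), "*") * pi / n_in)
  D <- D * sqrt(2 / n_in)
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' Compute Mel-frequency cepstral coefficients
#'
#' Standard MFCC front end: optional pre-emphasis, Hamming-windowed frames,
#' power spectrum, mel filterbank energies, log, orthonormal DCT-II.
#'
#' @param signal An [audio_signal()] at least one frame long.
#' @param config A [feature_config()].
#' @return An object of class `mfcc_matrix`: `values`
#'   (n_frames x n_mfcc matrix), `frame_hop_s`, `frame_len_s`, `n_coeffs`.
#' @export
compute_mfcc <- function(signal, config = feature_config()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(config, "feature_config"))
  sr <- signal$sample_rate
  frame_len <- round(config$frame_len_s * sr)
  hop <- round(config$hop_s * sr)
  x <- signal$samples
  if (length(x) < frame_len)
    vs_too_short(sprintf("signal (%d samples) shorter than one frame (%d)",
                         length(x), frame_len))
  if (config$preemphasis > 0)
    x <- c(x[1], x[-1] - config$preemphasis * x[-length(x)])

  n_frames <- (length(x) - frame_len) %/% hop + 1L
  idx <- outer(seq_len(frame_len), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(x[idx], nrow = frame_len)          # frame_len x n_frames
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(frame_len - 1L)) / (frame_len - 1L))
  frames <- frames * w

  n_fft <- 2^ceiling(log2(frame_len))
  padded <- rbind(frames, matrix(0, n_fft - frame_len, n_frames))
  spec <- stats::mvfft(padded)[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  power <- Mod(spec)^2

  fb <- mel_filterbank(config$n_mels, n_fft, sr)
  energies <- fb %*% power                            # n_mels x n_frames
  log_e <- log(pmax(energies, config$log_floor))
  D <- dct_matrix(config$n_mfcc, config$n_mels)
  cep <- t(D %*% log_e)                               # n_frames x n_mfcc
  colnames(cep) <- paste0("c", 0:(config$n_mfcc - 1L))
  structure(list(values = cep,
                 frame_hop_s = config$hop_s,
                 frame_len_s = config$frame_len_s,
                 n_coeffs = config$n_mfcc),
            class = "mfcc_matrix")
}

#' @export
print.mfcc_matrix <- function(x, ...) {
  cat(sprintf("<mfcc_matrix> %d frames x %d coefficients (hop %.0f ms)\n",
              nrow(x$values), x$n_coeffs, 1000 * x$frame_hop_s))
  invisible(x)
}
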