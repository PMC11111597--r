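# Modulation spectrum: the log power spectrum of each MFCC trajectory,
# capturing slow temporal dynamics of speech (syllable rate, pausing).
# The 20 lowest-frequency non-DC bins, averaged over coefficients, form
# the acoustic half of the classifier's feature vector.

#' Compute the modulation spectrum of an MFCC matrix
#'
#' For each cepstral coefficient independently: remove the temporal mean,
#' zero-pad (or truncate, with a warning) the trajectory to a fixed
#' analysis length so modulation bins align across utterances, take the
#' DFT along time and form the log magnitude-squared spectrum. Modulation
#' frequencies run from 0 (DC) to half the MFCC frame rate.
#'
#' @param mfcc An `mfcc_matrix` from [compute_mfcc()] with at least 4 frames.
#' @param n_fft Temporal analysis length in frames (default 512).
#' @param log_floor Floor under the power before the log, keeping silent
#'   coefficients finite.
#' @return An object of class `modulation_spectrum`: `log_power`
#'   (n_coeffs x n_mod_bins), `mod_freqs` (Hz, from 0, uniformly spaced),
#'   `n_frames` (pre-padding), `frame_hop_s`.
#' @export
compute_modulation_spectrum <- function(mfcc, n_fft = 512L,
                                        log_floor = 1e-12) {
  stopifnot(inherits(mfcc, "mfcc_matrix"))
  if (!is_count(n_fft) || n_fft < 8) vs_invalid("n_fft must be an integer >= 8")
  X <- mfcc$values
  n_frames <- nrow(X)
  if (n_frames < 4L)
    vs_too_short(sprintf("need >= 4 frames for a temporal spectrum, got %d",
                         n_frames))
  X <- sweep(X, 2L, colMeans(X))          # remove temporal mean per coefficient
  if (n_frames > n_fft) {
    warning(sprintf("trajectory of %d frames truncated to %d", n_frames, n_fft),
            call. = FALSE)
    X <- X[seq_len(n_fft), , drop = FALSE]
  } else if (n_frames < n_fft) {
    X <- rbind(X, matrix(0, n_fft - n_frames, ncol(X)))
  }
  spec <- stats::mvfft(X)[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  power <- Mod(spec)^2
  log_power <- t(log(pmax(power, log_floor)))     # n_coeffs x n_mod_bins
  rownames(log_power) <- colnames(mfcc$values)
  frame_rate <- 1 / mfcc$frame_hop_s
  structure(list(log_power = log_power,
                 mod_freqs = (0:(n_fft %/% 2L)) * frame_rate / n_fft,
                 n_frames = n_frames,
                 frame_hop_s = mfcc$frame_hop_s,
                 log_floor = log_floor),
            class = "modulation_spectrum")
}

#' @export
print.modulation_spectrum <- function(x, ...) {
  cat(sprintf(
    "<modulation_spectrum> %d coefficients x %d bins (0-%.1f Hz, %.3f Hz/bin)\n",
    nrow(x$log_power), ncol(x$log_power), max(x$mod_freqs),
    x$mod_freqs[2]))
  invisible(x)
}

#' Extract the lower-order modulation-spectrum components
#'
#' Averages log power across cepstral coefficients per modulation bin and
#' returns the `k` lowest-frequency non-DC bins in increasing frequency
#' order: a fixed-length acoustic feature vector comparable across
#' utterances.
#'
#' @param modspec A `modulation_spectrum`.
#' @param k Number of components (default 20).
#' @return An object of class `modspec_features`: `components` (length
#'   `k`), `bin_freqs` (Hz of the selected bins).
#' @export
extract_low_order_components <- function(modspec, k = 20L) {
  stopifnot(inherits(modspec, "modulation_spectrum"))
  n_bins <- ncol(modspec$log_power)
  if (!is_count(k) || k <= 0 || k >= n_bins)
    vs_invalid(sprintf("k must be in 1..%d (non-DC bins available)", n_bins - 1L))
  avg <- colMeans(modspec$log_power)
  sel <- 2:(k + 1L)                       # skip the DC bin
  structure(list(components = unname(avg[sel]),
                 bin_freqs = modspec$mod_freqs[sel]),
            class = "modspec_features")
}

#' @export
print.modspec_features <- function(x, ...) {
  cat(sprintf("<modspec_features> %d components, %.3f-%.3f Hz\n",
              length(x$components), min(x$bin_freqs), max(x$bin_freqs)))
  invisible(x)
}
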