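# RIFF WAV reading/writing and amplitude normalization.
#
# Recordings enter the pipeline as mono 16 kHz RIFF WAV; other sampling
# rates are resampled and multi-channel audio is averaged down to mono.
# Samples are represented internally as doubles in [-1, 1].

CANONICAL_RATE <- 16000L

#' Construct an audio signal
#'
#' Lightweight container for a mono amplitude time series with its sampling
#' rate. All pipeline audio is held in this form, as dimensionless
#' amplitudes nominally in \[-1, 1\].
#'
#' @param samples Numeric vector of amplitudes; must be finite.
#' @param sample_rate Sampling rate in Hz (positive integer).
#' @return An object of class `audio_signal` with fields `samples` and
#'   `sample_rate`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 440 * seq(0, 1, by = 1 / 16000)), 16000)
#' s
#' @export
audio_signal <- function(samples, sample_rate = CANONICAL_RATE) {
  if (!is.numeric(samples)) vs_invalid("samples must be numeric")
  if (length(samples) && !all(is.finite(samples)))
    vs_invalid("samples must all be finite")
  if (!is_count(sample_rate) || sample_rate <= 0)
    vs_invalid("sample_rate must be a positive integer (Hz)")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.integer(sample_rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %d Hz (%.3f s), RMS %.4g\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#' @param signal An `audio_signal`.
#' @return Duration in seconds.
#' @export
audio_duration <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  length(signal$samples) / signal$sample_rate
}

# Fourier-domain resampling (band-limited interpolation). Output length is
# round(n * rate_out / rate_in), matching the usual length contract.
resample_signal <- function(x, rate_in, rate_out) {
  n <- length(x)
  n_out <- round(n * rate_out / rate_in)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = n_out)
  keep <- min(floor(n / 2), floor(n_out / 2))
  Y[seq_len(keep + 1)] <- X[seq_len(keep + 1)]
  if (keep > 0)
    Y[(n_out - keep + 1):n_out] <- X[(n - keep + 1):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

read_u32 <- function(raw, off) {
  sum(as.integer(raw[off + 0:3]) * c(1, 256, 65536, 16777216))
}
read_u16 <- function(raw, off) {
  sum(as.integer(raw[off + 0:1]) * c(1, 256))
}

#' Read a RIFF WAV file
#'
#' Reads 16-bit PCM or 32-bit IEEE float WAV. Multi-channel audio is
#' averaged to mono; input at a rate other than `target_rate` is resampled
#' (band-limited, Fourier domain) with a warning.
#'
#' @param path Path to a RIFF WAV file.
#' @param target_rate Canonical pipeline rate in Hz; default 16000.
#' @return An [audio_signal()] at `target_rate`.
#' @export
read_wav <- function(path, target_rate = CANONICAL_RATE) {
  if (!is.character(path) || length(path) != 1L)
    vs_invalid("path must be a single file path")
  if (!file.exists(path)) vs_not_found(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 44 ||
      rawToChar(raw[1:4]) != "RIFF" || rawToChar(raw[9:12]) != "WAVE")
    vs_format(sprintf("not a RIFF WAV file: %s", path))

  # walk chunks
  off <- 13L
  fmt <- NULL
  data_raw <- NULL
  while (off + 8L <= length(raw)) {
    id <- rawToChar(raw[off + 0:3])
    size <- read_u32(raw, off + 4L)
    body_off <- off + 8L
    if (body_off + size - 1L > length(raw))
      size <- length(raw) - body_off + 1L  # tolerate truncated final chunk size
    if (id == "fmt ") {
      fmt <- list(
        audio_format = read_u16(raw, body_off),
        n_channels   = read_u16(raw, body_off + 2L),
        sample_rate  = read_u32(raw, body_off + 4L),
        bits         = read_u16(raw, body_off + 14L)
      )
    } else if (id == "data") {
      data_raw <- raw[body_off + seq_len(size) - 1L]
    }
    off <- body_off + size + (size %% 2L)  # chunks are word-aligned
  }
  if (is.null(fmt) || is.null(data_raw))
    vs_format(sprintf("missing fmt/data chunk in WAV file: %s", path))

  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    n <- length(data_raw) %/% 2L
    s <- readBin(data_raw, "integer", n = n, size = 2L,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    n <- length(data_raw) %/% 4L
    s <- readBin(data_raw, "double", n = n, size = 4L, endian = "little")
  } else {
    vs_format(sprintf("unsupported WAV encoding (format %d, %d bits); %s",
                      fmt$audio_format, fmt$bits,
                      "only PCM16 and float32 are supported"))
  }

  if (fmt$n_channels > 1L) {
    n_frames <- length(s) %/% fmt$n_channels
    s <- rowMeans(matrix(s[seq_len(n_frames * fmt$n_channels)],
                         ncol = fmt$n_channels, byrow = TRUE))
  }
  if (fmt$sample_rate != target_rate) {
    warning(sprintf("resampling %d Hz -> %d Hz: %s",
                    fmt$sample_rate, target_rate, basename(path)),
            call. = FALSE)
    s <- resample_signal(s, fmt$sample_rate, target_rate)
  }
  audio_signal(s, target_rate)
}

#' Write an audio signal as 16-bit PCM RIFF WAV
#'
#' Samples outside \[-1, 1\] are clipped at the 16-bit boundary.
#'
#' @param signal An [audio_signal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  s <- pmin(pmax(signal$samples, -1), 32767 / 32768)
  pcm <- as.integer(round(s * 32768))
  pcm <- pmin(pmax(pcm, -32768L), 32767L)
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")             # PCM
  writeBin(1L, con, size = 2L, endian = "little")             # mono
  writeBin(as.integer(signal$sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(signal$sample_rate * 2L), con, size = 4L,
           endian = "little")                                 # byte rate
  writeBin(2L, con, size = 2L, endian = "little")             # block align
  writeBin(16L, con, size = 2L, endian = "little")            # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Power-normalize an audio signal to a target RMS level
#'
#' Rescales the waveform by a single positive factor so that its root mean
#' square amplitude equals `target_rms`; the waveform shape is preserved.
#' Normalization is per-utterance and idempotent.
#'
#' @param signal An [audio_signal()].
#' @param target_rms Target RMS amplitude (default 0.1).
#' @return The rescaled [audio_signal()].
#' @export
power_normalize <- function(signal, target_rms = 0.1) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!is.numeric(target_rms) || length(target_rms) != 1L || target_rms <= 0)
    vs_invalid("target_rms must be a positive number")
  if (!length(signal$samples)) vs_degenerate("empty signal cannot be normalized")
  rms <- sqrt(mean(signal$samples^2))
  if (rms < 1e-12)
    vs_degenerate("silent (near-zero RMS) signal cannot be normalized")
  audio_signal(signal$samples * (target_rms / rms), signal$sample_rate)
}
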