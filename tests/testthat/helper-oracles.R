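# Independent oracles, deliberately coded as plain loops / enumeration so
# they share no code path with the package implementation.

# O(N^2) discrete Fourier transform of one series
naive_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1L), function(k) {
    s <- 0 + 0i
    for (t in 0:(n - 1L)) s <- s + x[t + 1L] * exp(-2i * pi * k * t / n)
    s
  }, complex(1))
}

# Scalar-loop MFCC with the package's default settings (25 ms / 10 ms
# frames, pre-emphasis 0.97, Hamming, 26 HTK mel filters, DCT-II ortho,
# 13 coefficients), written without vectorized helpers.
naive_mfcc <- function(samples, sr = 16000, frame_len = 400L, hop = 160L,
                       n_mels = 26L, n_mfcc = 13L, pre = 0.97,
                       floor_ = 1e-12) {
  x <- numeric(length(samples))
  x[1] <- samples[1]
  for (t in 2:length(samples)) x[t] <- samples[t] - pre * samples[t - 1L]
  n_fft <- 512L
  n_frames <- (length(x) - frame_len) %/% hop + 1L
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(mel(0), mel(sr / 2), length.out = n_mels + 2L))
  out <- matrix(0, n_frames, n_mfcc)
  for (fr in seq_len(n_frames)) {
    seg <- x[((fr - 1L) * hop + 1L):((fr - 1L) * hop + frame_len)]
    for (i in seq_len(frame_len))
      seg[i] <- seg[i] * (0.54 - 0.46 * cos(2 * pi * (i - 1) / (frame_len - 1)))
    spec <- fft(c(seg, rep(0, n_fft - frame_len)))
    pw <- Mod(spec[1:(n_fft / 2 + 1L)])^2
    fb_energy <- numeric(n_mels)
    for (m in seq_len(n_mels)) {
      for (b in 1:(n_fft / 2 + 1L)) {
        f <- (b - 1) * sr / n_fft
        w <- 0
        if (f >= pts[m] && f <= pts[m + 1L])
          w <- (f - pts[m]) / (pts[m + 1L] - pts[m])
        else if (f > pts[m + 1L] && f <= pts[m + 2L])
          w <- (pts[m + 2L] - f) / (pts[m + 2L] - pts[m + 1L])
        fb_energy[m] <- fb_energy[m] + w * pw[b]
      }
    }
    loge <- log(pmax(fb_energy, floor_))
    for (k in 0:(n_mfcc - 1L)) {
      s <- 0
      for (m in 0:(n_mels - 1L))
        s <- s + loge[m + 1L] * cos(pi * k * (m + 0.5) / n_mels)
      scale <- if (k == 0) sqrt(1 / n_mels) else sqrt(2 / n_mels)
      out[fr, k + 1L] <- s * scale
    }
  }
  out
}

# Exhaustive 2x2 two-sided exact test (probability-mass rule) via choose()
brute_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  denom <- choose(n, c1)
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- sapply(support, function(a) choose(r1, a) * choose(r2, c1 - a) / denom)
  p_obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force r x 2 exact test: enumerate first-column cells by expand.grid
brute_fisher_rx2 <- function(tab) {
  r <- nrow(tab)
  rs <- rowSums(tab); c1 <- sum(tab[, 1]); n <- sum(tab)
  grids <- expand.grid(lapply(rs, function(m) 0:min(m, c1)))
  grids <- grids[rowSums(grids) == c1, , drop = FALSE]
  logp <- function(col1) {
    cells <- c(col1, rs - col1)
    sum(lgamma(rs + 1)) + lgamma(c1 + 1) + lgamma(n - c1 + 1) -
      lgamma(n + 1) - sum(lgamma(cells + 1))
  }
  lps <- apply(grids, 1L, logp)
  lp_obs <- logp(tab[, 1])
  sum(exp(lps[lps <= lp_obs + log1p(1e-7)]))
}

make_sine <- function(freq = 440, dur = 1, sr = 16000, amp = 0.5) {
  audio_signal(amp * sin(2 * pi * freq * (0:(dur * sr - 1)) / sr), sr)
}
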