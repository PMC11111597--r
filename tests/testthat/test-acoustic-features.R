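# MFCC front end, modulation spectrum, low-order component extraction

test_that("digital silence yields identical coefficients in every frame", {
  s <- audio_signal(rep(0, 16000))
  m <- compute_mfcc(s)
  expect_true(all(is.finite(m$values)))
  expect_lt(max(apply(m$values, 2L, function(col) diff(range(col)))), 1e-12)
})

test_that("MFCC matches an independently coded scalar-loop reference", {
  set.seed(11)
  s <- audio_signal(0.3 * sin(2 * pi * 440 * (0:7999) / 16000) +
                      0.05 * rnorm(8000))
  m <- compute_mfcc(s)
  ref <- naive_mfcc(s$samples)
  expect_equal(dim(m$values), dim(ref))
  expect_lt(max(abs(m$values - ref)), 1e-6)
})

test_that("tone and noise produce distinct coefficient trajectories", {
  tone <- compute_mfcc(make_sine(440))
  set.seed(5)
  noise <- compute_mfcc(audio_signal(0.3 * rnorm(16000)))
  expect_gt(mean(abs(tone$values - noise$values)), 0.1)
})

test_that("inputs shorter than one frame are rejected", {
  expect_error(compute_mfcc(audio_signal(rep(0.1, 160))),   # 10 ms
               class = "vs_too_short_error")
})

test_that("constant MFCC trajectories floor the whole modulation spectrum", {
  m <- compute_mfcc(audio_signal(rep(0, 16000)))
  ms <- compute_modulation_spectrum(m)
  expect_true(all(abs(ms$log_power - log(1e-12)) < 1e-6))
  expect_identical(ms$mod_freqs[1], 0)
  expect_true(all(diff(ms$mod_freqs) > 0))
})

test_that("a 4 Hz sinusoidal trajectory peaks at the bin nearest 4 Hz", {
  # 100 frames/s for 2 s: c(t) = sin(2*pi*4*t)
  vals <- matrix(sin(2 * pi * 4 * (0:199) / 100), ncol = 1L)
  m <- structure(list(values = vals, frame_hop_s = 0.01,
                      frame_len_s = 0.025, n_coeffs = 1L),
                 class = "mfcc_matrix")
  ms <- compute_modulation_spectrum(m, n_fft = 512L)
  non_dc <- ms$log_power[1, -1]
  peak_freq <- ms$mod_freqs[-1][which.max(non_dc)]
  expect_lt(abs(peak_freq - 4), ms$mod_freqs[2] + 1e-9)
})

test_that("modulation power satisfies Parseval against the centered series", {
  set.seed(3)
  n <- 64L
  vals <- matrix(rnorm(n * 3L), n, 3L)
  m <- structure(list(values = vals, frame_hop_s = 0.01,
                      frame_len_s = 0.025, n_coeffs = 3L),
                 class = "mfcc_matrix")
  ms <- compute_modulation_spectrum(m, n_fft = n)    # no padding
  for (j in 1:3) {
    pw <- exp(ms$log_power[j, ])
    # reconstruct the full two-sided sum from the one-sided spectrum
    total <- pw[1] + pw[n / 2 + 1] + 2 * sum(pw[2:(n / 2)])
    centered <- vals[, j] - mean(vals[, j])
    expect_equal(total, n * sum(centered^2), tolerance = 1e-9)
  }
})

test_that("fast transform agrees with a brute-force DFT on small inputs", {
  set.seed(9)
  for (n in c(8L, 17L, 64L)) {
    vals <- matrix(rnorm(n * 2L), n, 2L)
    m <- structure(list(values = vals, frame_hop_s = 0.01,
                        frame_len_s = 0.025, n_coeffs = 2L),
                   class = "mfcc_matrix")
    ms <- compute_modulation_spectrum(m, n_fft = n)
    for (j in 1:2) {
      centered <- vals[, j] - mean(vals[, j])
      ref <- Mod(naive_dft(centered)[1:(n %/% 2 + 1L)])^2
      expect_equal(exp(ms$log_power[j, ]), pmax(ref, 1e-12),
                   tolerance = 1e-9)
    }
  }
})

test_that("features are invariant to circular time shifts of the frames", {
  set.seed(21)
  n <- 128L
  vals <- matrix(rnorm(n * 4L), n, 4L)
  mk <- function(v) structure(list(values = v, frame_hop_s = 0.01,
                                   frame_len_s = 0.025, n_coeffs = 4L),
                              class = "mfcc_matrix")
  f1 <- extract_low_order_components(
    compute_modulation_spectrum(mk(vals), n_fft = n), k = 20L)
  shifted <- vals[c(31:n, 1:30), , drop = FALSE]
  f2 <- extract_low_order_components(
    compute_modulation_spectrum(mk(shifted), n_fft = n), k = 20L)
  expect_lt(max(abs(f1$components - f2$components)), 1e-6)
})

test_that("scaling MFCCs by c shifts non-floored log power by 2*log(c)", {
  set.seed(4)
  n <- 64L
  vals <- matrix(rnorm(n * 2L), n, 2L)
  mk <- function(v) structure(list(values = v, frame_hop_s = 0.01,
                                   frame_len_s = 0.025, n_coeffs = 2L),
                              class = "mfcc_matrix")
  ms1 <- compute_modulation_spectrum(mk(vals), n_fft = n)
  ms2 <- compute_modulation_spectrum(mk(vals * 3), n_fft = n)
  not_floored <- ms1$log_power > log(1e-12) + 1
  expect_equal(ms2$log_power[not_floored] - ms1$log_power[not_floored],
               rep(2 * log(3), sum(not_floored)), tolerance = 1e-9)
})

test_that("low-order extraction returns k non-DC bins in frequency order", {
  m <- compute_mfcc(make_sine(300, dur = 2))
  ms <- compute_modulation_spectrum(m)
  fc <- extract_low_order_components(ms, k = 20L)
  expect_length(fc$components, 20L)
  expect_true(all(is.finite(fc$components)))
  expect_equal(fc$bin_freqs, ms$mod_freqs[2:21])
  # identical rows average to themselves
  ms2 <- ms
  ms2$log_power <- matrix(rep(ms$log_power[1, ], each = nrow(ms$log_power)),
                          nrow = nrow(ms$log_power))
  fc2 <- extract_low_order_components(ms2, k = 5L)
  expect_equal(fc2$components, unname(ms$log_power[1, 2:6]))
})

test_that("degenerate modulation inputs are rejected", {
  m3 <- structure(list(values = matrix(rnorm(9), 3L, 3L), frame_hop_s = 0.01,
                       frame_len_s = 0.025, n_coeffs = 3L),
                  class = "mfcc_matrix")
  expect_error(compute_modulation_spectrum(m3), class = "vs_too_short_error")
  ms <- suppressWarnings(
    compute_modulation_spectrum(compute_mfcc(make_sine()), n_fft = 32L))
  expect_error(extract_low_order_components(ms, k = 0L),
               class = "vs_invalid_error")
  expect_error(extract_low_order_components(ms, k = 17L),  # == n_mod_bins
               class = "vs_invalid_error")
  expect_warning(
    compute_modulation_spectrum(compute_mfcc(make_sine(dur = 1)), n_fft = 16L),
    "truncated")
})
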