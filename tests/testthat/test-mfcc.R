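test_that("Bartlett window satisfies its boundary, peak and symmetry identities", {
  expect_equal(bartlett_window(4), c(0, 0.5, 1, 0.5, 0))
  for (N in c(2, 5, 99, 100)) {
    w <- bartlett_window(N)
    expect_length(w, N + 1)
    expect_equal(w[1], 0)
    expect_equal(w[N + 1], 0)
    if (N %% 2 == 0) expect_equal(w[N / 2 + 1], 1)
    expect_equal(w, rev(w))  # w(n) = w(N - n)
  }
  expect_error(bartlett_window(1), class = "pcg_bad_window")
})

test_that("framing yields 298 frames with 60% overlap at the standard setup", {
  rec <- std_recording(3)
  fr <- frame_signal(rec)
  expect_identical(nrow(fr$frames), 298L)
  expect_identical(fr$frame_len, 100)
  expect_identical(fr$hop, 40)
  expect_equal((fr$frame_len - fr$hop) / fr$frame_len, 0.6)
  # windowing: each row is the raw frame times the Bartlett window
  expect_equal(fr$frames[1, ], rec$samples[1:100] * bartlett_window(99))
  expect_equal(fr$frames[5, ], rec$samples[161:260] * bartlett_window(99))

  one <- frame_signal(pcg_recording(rnorm(100), 4000, "one"))
  expect_identical(nrow(one$frames), 1L)
  expect_error(frame_signal(pcg_recording(rnorm(50), 4000, "tiny")),
               class = "pcg_signal_too_short")
})

test_that("magnitude spectra match a naive DFT and satisfy Parseval", {
  # independent oracle: O(N^2) DFT on a random 16-sample frame
  set.seed(11)
  x <- rnorm(16)
  naive_dft <- function(x) {
    N <- length(x)
    vapply(0:(N - 1), function(k)
      sum(complex(real = x, imaginary = 0) *
            exp(-2i * pi * k * (0:(N - 1)) / N)), complex(1))
  }
  X <- naive_dft(x)
  fr <- structure(list(frames = matrix(x, 1), frame_len = 16L, hop = 16L, fs = 4000),
                  class = "pcg_frames")
  spec <- magnitude_spectrum(fr, n_fft = 16)
  expect_equal(as.numeric(spec), Mod(X)[1:9], tolerance = 1e-9)
  # Parseval over the full two-sided spectrum
  expect_equal(sum(x^2), sum(Mod(X)^2) / 16, tolerance = 1e-9)

  # zero frame -> zero spectrum; unwindowed unit impulse -> flat magnitude 1
  frz <- structure(list(frames = rbind(rep(0, 16), c(1, rep(0, 15))),
                        frame_len = 16L, hop = 16L, fs = 4000),
                   class = "pcg_frames")
  sp <- magnitude_spectrum(frz, 16)
  expect_true(all(sp[1, ] == 0))
  expect_equal(sp[2, ], rep(1, 9))
})

test_that("mel scale follows m = 2595 log10(1 + f/700) and inverts cleanly", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2))
  expect_gt(hz_to_mel(2000), hz_to_mel(1000))
  f <- c(0.5, 10, 137, 700, 1999.5)
  expect_equal(mel_to_hz(hz_to_mel(f)), f, tolerance = 1e-9)
  expect_error(hz_to_mel(-1), class = "pcg_bad_freq")
})

test_that("mel filter bank rows are unit-peak triangles covering the band", {
  bank <- mel_filterbank(20, n_fft = 128, fs = 4000)
  expect_identical(nrow(bank$B), 20L)
  expect_equal(unname(apply(bank$B, 1, max)), rep(1, 20))
  expect_true(all(diff(bank$centers_hz) > 0))
  # brute-force coverage check on a 64-bin bank: every bin strictly between
  # the first and last edge bins has positive weight in some filter
  b64 <- mel_filterbank(12, n_fft = 64, fs = 4000)
  lo <- b64$bins[1]; hi <- b64$bins[length(b64$bins)]
  interior <- (lo + 1):(hi - 1)
  covered <- vapply(interior, function(k) any(b64$B[, k + 1] > 0), logical(1))
  expect_true(all(covered))
  expect_error(mel_filterbank(60, n_fft = 64, fs = 4000),
               class = "pcg_filterbank_resolution")
})

test_that("mel log energies follow the weighted power sum with a finite floor", {
  bank <- mel_filterbank(20, n_fft = 128, fs = 4000)
  zero <- matrix(0, 2, 65)
  El <- mel_log_energies(zero, bank)
  expect_true(all(is.finite(El)))
  expect_true(all(El == log(1e-10)))

  spec <- matrix(runif(65, 0.5, 1), 1)
  e1 <- exp(mel_log_energies(spec, bank))
  e2 <- exp(mel_log_energies(2 * spec, bank))
  expect_equal(e2 / e1, matrix(4, 1, 20), tolerance = 1e-9)

  # single-bin spectrum: energy is that bin's power times the filter weight
  m <- 7; kbin <- which(bank$B[m, ] == 0.5)[1]
  skip_if(is.na(kbin))
  s <- matrix(0, 1, 65); s[1, kbin] <- sqrt(3)
  expect_equal(exp(mel_log_energies(s, bank))[1, m], 0.5 * 3, tolerance = 1e-9)
  expect_error(mel_log_energies(matrix(0, 1, 33), bank), class = "pcg_shape_mismatch")
})

test_that("cepstral DCT matches direct evaluation and is linear", {
  # constant log-energy vector: all kept coefficients (n >= 1) vanish
  El <- matrix(3.7, 1, 20)
  expect_equal(as.numeric(dct_cepstra(El, 20)), rep(0, 20), tolerance = 1e-12)
  # M=4, Elog = (1,0,0,0): coefficient 1 = cos(pi/8)
  expect_equal(as.numeric(dct_cepstra(matrix(c(1, 0, 0, 0), 1), 1)), cos(pi / 8))
  # linearity
  a <- matrix(rnorm(40), 2); b <- matrix(rnorm(40), 2)
  expect_equal(dct_cepstra(a + b, 12), dct_cepstra(a, 12) + dct_cepstra(b, 12))
  expect_error(dct_cepstra(a, 21), class = "pcg_bad_ncoef")
})

test_that("the DCT is invertible at full order after orthonormal rescaling", {
  M <- 20
  set.seed(21)
  El <- matrix(rnorm(5 * M), 5, M)
  C <- dct_cepstra(El, M)
  # orthonormal DCT-II: row 0 = sqrt(1/M), rows n>=1 = sqrt(2/M) cos(...)
  c0 <- rowSums(El) * sqrt(1 / M)
  Corth <- cbind(c0, C * sqrt(2 / M))
  D <- rbind(sqrt(1 / M),
             sqrt(2 / M) * t(sapply(1:(M - 1), function(n)
               cos(n * ((1:M) - 0.5) * pi / M))))
  Dfull <- rbind(D, sqrt(2 / M) * cos(M * ((1:M) - 0.5) * pi / M))
  expect_equal(Corth %*% Dfull, El, tolerance = 1e-8)
})

test_that("MFCC summary features have the stated dimensions and invariances", {
  rec <- std_recording(5)
  for (n in c(8, 26)) {
    f <- mfcc_features(rec, n)
    expect_length(f, 2 * n)
    expect_identical(names(f)[1:2], c("mfcc01_mean", "mfcc01_std"))
  }
  # periodic signal with period = hop: all frames identical, stds all 0
  per <- pcg_recording(rep(sin(2 * pi * (0:39) / 40), 300), 4000, "per")
  fper <- mfcc_features(per, 8)
  expect_equal(unname(fper[grepl("_std$", names(fper))]), rep(0, 8), tolerance = 1e-8)
  # amplitude scaling only shifts the excluded 0th coefficient
  sc <- rec; sc$samples <- rec$samples * 3.7
  expect_lt(max(abs(mfcc_features(sc, 12) - mfcc_features(rec, 12))), 1e-6)
})
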