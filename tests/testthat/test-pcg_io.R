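test_that("read_wav scales integer PCM by two's-complement full scale", {
  # hand-written 4-sample file: peak 16384 must read back as 0.5
  tf <- withr::local_tempfile(fileext = ".wav")
  write_pcm16_fixture(tf, c(16384L, -16384L, 8192L, 0L))
  rec <- read_wav(tf)
  expect_equal(rec$samples, c(0.5, -0.5, 0.25, 0), tolerance = 1e-12)
  expect_equal(rec$fs, 4000)
})

test_that("read_wav reads zeros, averages stereo, and raises named errors", {
  tf <- withr::local_tempfile(fileext = ".wav")
  write_pcm16_fixture(tf, integer(4000))
  rec <- read_wav(tf)
  expect_length(rec$samples, 4000)
  expect_true(all(rec$samples == 0))

  # stereo 0.2 / 0.4 -> mono 0.3 (interleaved L,R frames)
  st <- withr::local_tempfile(fileext = ".wav")
  lr <- rep(c(round(0.2 * 32768), round(0.4 * 32768)), 100)
  write_pcm16_fixture(st, lr, channels = 2L)
  rec2 <- read_wav(st)
  expect_length(rec2$samples, 100)
  expect_equal(rec2$samples, rep(0.3, 100), tolerance = 1e-4)

  expect_error(read_wav(file.path(tempdir(), "nope.wav")), class = "pcg_missing_file")
  bad <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:64), bad)
  expect_error(read_wav(bad), class = "pcg_bad_wav")
  emp <- withr::local_tempfile(fileext = ".wav")
  write_pcm16_fixture(emp, integer(0))
  expect_error(read_wav(emp), class = "pcg_empty_audio")
})

test_that("write_wav/read_wav round-trips within 16-bit quantization", {
  rec <- pcg_recording(sin(2 * pi * 37 * (0:3999) / 4000) * 0.8, 4000, "rt")
  tf <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, tf)
  back <- read_wav(tf)
  expect_equal(back$fs, 4000)
  expect_lt(max(abs(back$samples - rec$samples)), 2^-15 + 1e-9)
})

test_that("resampling hits the target rate and preserves spectral content", {
  rec <- pcg_recording(rnorm(4000), 4000, "id")
  expect_identical(resample_recording(rec, 4000), rec)

  rec8 <- pcg_recording(rnorm(8000), 8000, "half")
  expect_length(resample_recording(rec8, 4000)$samples, 4000)

  # 100 Hz tone at 44100 Hz: dominant FFT bin must stay at 100 Hz
  t <- (0:44099) / 44100
  tone <- pcg_recording(sin(2 * pi * 100 * t), 44100, "tone")
  rs <- resample_recording(tone, 4000)
  expect_equal(rs$fs, 4000)
  expect_length(rs$samples, 4000)  # duration preserved
  mag <- Mod(stats::fft(rs$samples))[1:2000]
  expect_equal(which.max(mag) - 1L, 100L)  # 1-s signal: bin index = Hz

  expect_error(resample_recording(rec, -1), class = "pcg_bad_fs")
})

test_that("peak normalization scales to unit peak and rejects silence", {
  rec <- pcg_recording(c(0.1, -0.5, 0.25), 4000, "p")
  out <- peak_normalize(rec)
  expect_equal(max(abs(out$samples)), 1)
  expect_equal(out$samples, rec$samples * 2)
  expect_identical(peak_normalize(out)$samples, out$samples)
  neg <- peak_normalize(pcg_recording(rep(-0.25, 10), 4000, "n"))
  expect_equal(neg$samples, rep(-1, 10))
  expect_error(peak_normalize(pcg_recording(rep(0, 5), 4000, "z")),
               class = "pcg_zero_signal")
})

test_that("label binarization reproduces the pooled abnormal counts", {
  man <- pcg_manifest(sprintf("r%03d", 1:312),
                      label = rep(c("normal", "murmur", "extrasystole"),
                                  c(200, 66, 46)))
  bin <- binarize_labels(man)
  expect_equal(class_counts(bin), c(abnormal = 112L, normal = 200L))
  expect_equal(nrow(bin), 312L)

  allnorm <- pcg_manifest(c("a", "b"), label = c("normal", "normal"))
  expect_equal(class_counts(binarize_labels(allnorm)), c(normal = 2L))
  few <- binarize_labels(pcg_manifest(letters[1:5],
                                      label = rep(c("murmur", "extrasystole"), c(3, 2))))
  expect_equal(class_counts(few), c(abnormal = 5L))
  expect_error(binarize_labels(pcg_manifest("x", label = "abnormal")),
               class = "pcg_bad_label")
})

test_that("class balancing undersamples the majority to the minority count", {
  man <- binarize_labels(pcg_manifest(sprintf("r%03d", 1:312),
                                      label = rep(c("normal", "murmur", "extrasystole"),
                                                  c(200, 66, 46))))
  bal <- balance_classes(man, seed = 42)
  expect_equal(class_counts(bal), c(abnormal = 112L, normal = 112L))
  expect_equal(nrow(bal), 224L)
  # minority rows untouched
  expect_setequal(bal$record_id[bal$label == "abnormal"],
                  man$record_id[man$label == "abnormal"])
  # determinism and no-op on balanced input
  expect_identical(balance_classes(man, seed = 42), bal)
  expect_false(identical(balance_classes(man, seed = 43)$record_id, bal$record_id))
  even <- pcg_manifest(letters[1:10], label = rep(c("normal", "abnormal"), each = 5))
  expect_identical(balance_classes(even, seed = 1), even)
  expect_error(balance_classes(pcg_manifest("a", label = "normal"), 1),
               class = "pcg_empty_class")
})

test_that("manifest CSV round-trips and validates its schema", {
  man <- pcg_manifest(c("a", "b"), path = c("/x/a.wav", "/x/b.wav"),
                      label = c("normal", "murmur"))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_manifest(man, tf)
  back <- read_manifest(tf)
  expect_equal(as.data.frame(back), as.data.frame(man))
  expect_error(pcg_manifest(c("a", "a"), label = c("normal", "normal")),
               class = "pcg_manifest_dup")
})
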