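# Shared fixtures, all generated in code at test time.

# A standardized 3-s recording (labelled, peak-normalized, 12000 samples).
std_recording <- function(seed = 1, class = "normal", label = NULL) {
  gen <- switch(class, normal = synth_normal, murmur = synth_murmur,
                extrasystole = synth_extrasystole)
  rec <- gen(synth_config(duration_s = 4), seed = seed)
  if (!is.null(label)) rec$label <- label
  standardize_duration(peak_normalize(rec))
}

# Small in-memory binarized corpus as a list of standardized recordings.
small_corpus <- function(n_normal = 12, n_abnormal = 12, seed0 = 100) {
  n_mur <- ceiling(n_abnormal / 2)
  recs <- c(
    lapply(seq_len(n_normal), function(i) std_recording(seed0 + i, "normal", "normal")),
    lapply(seq_len(n_mur), function(i) std_recording(seed0 + 500 + i, "murmur", "abnormal")),
    lapply(seq_len(n_abnormal - n_mur), function(i)
      std_recording(seed0 + 900 + i, "extrasystole", "abnormal")))
  for (i in seq_along(recs)) recs[[i]]$record_id <- sprintf("rec_%03d", i)
  recs
}

# Feature table with two informative columns (f01 tracks the label, f02 is a
# noisy copy) among pure-noise columns; used by the selection tests.
signal_table <- function(n = 60, p = 20, seed = 7) {
  stopifnot(p >= 3)
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- y * 2 + rnorm(n, sd = 0.1)
  x[, 2] <- y * 2 + rnorm(n, sd = 0.6)
  colnames(x) <- sprintf("f%02d", seq_len(p))
  cbind(data.frame(record_id = sprintf("r%03d", seq_len(n)), stringsAsFactors = FALSE),
        as.data.frame(x), data.frame(label = y))
}

# Hand-written 16-bit PCM WAV: a minimal RIFF file assembled byte by byte,
# independent of write_wav().
write_pcm16_fixture <- function(path, samples_int, fs = 4000, channels = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples_int)
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + 2L * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(1L); w16(channels); w32(fs); w32(fs * 2L * channels); w16(2L * channels); w16(16L)
  writeChar("data", con, eos = NULL); w32(2L * n)
  writeBin(as.integer(samples_int), con, size = 2L, endian = "little")
  path
}
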