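#' Construct a phonocardiogram recording
#'
#' A recording is a real-valued amplitude sequence together with its sampling
#' rate, an opaque record identifier and an optional class label.
#'
#' @param samples Numeric vector of amplitudes (dimensionless).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param record_id Opaque identifier string.
#' @param label Class label: one of `"normal"`, `"murmur"`, `"extrasystole"`,
#'   `"abnormal"`, or `NA` when unlabeled.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, fs, record_id = NA_character_, label = NA_character_) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop(pcg_error("pcg_empty_audio", "recording must contain at least one sample"))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop(pcg_error("pcg_bad_fs", "sampling rate must be a positive scalar"))
  if (!is.na(label) && !label %in% c("normal", "murmur", "extrasystole", "abnormal"))
    stop(pcg_error("pcg_bad_label", sprintf("unknown label '%s'", label)))
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 record_id = as.character(record_id), label = as.character(label)),
            class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> id=%s label=%s fs=%g Hz n=%d (%.3f s)\n",
              x$record_id, x$label, x$fs, length(x$samples), length(x$samples) / x$fs))
  invisible(x)
}

pcg_error <- function(class, message) {
  errorCondition(message, class = c(class, "pcg_error"))
}

duration_s <- function(rec) length(rec$samples) / rec$fs

## ---- WAV reading/writing -------------------------------------------------
## Minimal RIFF/WAVE codec: PCM 8/16/24/32-bit integer and IEEE float 32/64,
## little-endian, any channel count (collapsed to mono by averaging).

#' Read a WAV file as a phonocardiogram recording
#'
#' Samples are scaled to `[-1, 1]` (integer PCM divided by its full-scale
#' magnitude, e.g. 16-bit values by 32768). Multi-channel audio is collapsed
#' to mono by averaging channels; the sampling rate is taken from the header.
#'
#' @param path Path to a RIFF/WAVE file (PCM integer or IEEE float).
#' @param record_id Identifier to attach; defaults to the file name.
#' @param label Optional class label.
#' @return A [pcg_recording()].
#' @export
read_wav <- function(path, record_id = basename(path), label = NA_character_) {
  if (!file.exists(path))
    stop(pcg_error("pcg_missing_file", sprintf("WAV file not found: %s", path)))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 44L || rawToChar(raw[1:4]) != "RIFF" || rawToChar(raw[9:12]) != "WAVE")
    stop(pcg_error("pcg_bad_wav", sprintf("not a RIFF/WAVE file: %s", path)))

  u32 <- function(at) sum(as.integer(raw[at:(at + 3L)]) * c(1, 256, 65536, 16777216))
  u16 <- function(at) sum(as.integer(raw[at:(at + 1L)]) * c(1, 256))

  # walk chunks for fmt and data
  pos <- 13L
  fmt <- NULL; data_at <- NULL; data_len <- NULL
  while (pos + 7L <= length(raw)) {
    cid <- rawToChar(raw[pos:(pos + 3L)])
    csz <- u32(pos + 4L)
    body <- pos + 8L
    if (cid == "fmt ") {
      fmt <- list(audio_format = u16(body), n_channels = u16(body + 2L),
                  sample_rate = u32(body + 4L), bits = u16(body + 14L))
      if (fmt$audio_format == 65534L && csz >= 40L)  # WAVE_FORMAT_EXTENSIBLE
        fmt$audio_format <- u16(body + 24L)
    } else if (cid == "data") {
      data_at <- body; data_len <- csz
    }
    pos <- body + csz + (csz %% 2L)  # chunks are word-aligned
  }
  if (is.null(fmt) || is.null(data_at))
    stop(pcg_error("pcg_bad_wav", sprintf("missing fmt/data chunk: %s", path)))
  data_len <- min(data_len, length(raw) - data_at + 1L)
  bytes <- fmt$bits %/% 8L
  n_total <- data_len %/% (bytes * fmt$n_channels) * fmt$n_channels
  if (n_total == 0L)
    stop(pcg_error("pcg_empty_audio", sprintf("zero-length audio: %s", path)))
  con <- rawConnection(raw[data_at:(data_at + n_total * bytes - 1L)])
  on.exit(close(con))
  x <- if (fmt$audio_format == 3L) {
    readBin(con, "double", n = n_total, size = bytes, endian = "little")
  } else if (fmt$audio_format == 1L) {
    if (bytes == 1L) {
      (as.numeric(readBin(con, "integer", n = n_total, size = 1L, signed = FALSE)) - 128) / 128
    } else if (bytes == 3L) {
      b <- matrix(as.integer(readBin(con, "raw", n = n_total * 3L)), nrow = 3L)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      ifelse(v >= 2^23, v - 2^24, v) / 2^23
    } else {
      readBin(con, "integer", n = n_total, size = bytes, endian = "little") / 2^(fmt$bits - 1L)
    }
  } else {
    stop(pcg_error("pcg_bad_wav", sprintf("unsupported WAV format code %d", fmt$audio_format)))
  }
  if (fmt$n_channels > 1L)
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  pcg_recording(x, fmt$sample_rate, record_id = record_id, label = label)
}

#' Write a recording as a 16-bit PCM mono WAV file
#'
#' Amplitudes are quantized by the two's-complement full scale (32768) and
#' clipped to the 16-bit range, so a read/write round trip is exact to
#' within one quantization step (2^-15).
#'
#' @param rec A [pcg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "pcg_recording"))
  pcm <- as.integer(pmin(pmax(round(rec$samples * 32768), -32768), 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w_u32(36L + 2L * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_u32(16L)
  w_u16(1L); w_u16(1L); w_u32(rec$fs); w_u32(rec$fs * 2L); w_u16(2L); w_u16(16L)
  writeChar("data", con, eos = NULL); w_u32(2L * n)
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

## ---- amplitude and rate standardization ----------------------------------

#' Resample a recording to a target rate
#'
#' Polyphase resampling (via [signal::resample()]) by the rational factor
#' `target_fs / fs`; a no-op when the rates already match. The wavelet band
#' edges downstream assume 4000 Hz, the default target.
#'
#' @param rec A [pcg_recording()].
#' @param target_fs Target sampling rate in Hz.
#' @return The resampled recording, duration preserved to within one sample.
#' @export
resample_recording <- function(rec, target_fs = 4000) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop(pcg_error("pcg_bad_fs", "target_fs must be a positive scalar"))
  if (rec$fs == target_fs) return(rec)
  g <- rational_gcd(target_fs, rec$fs)
  y <- signal::resample(rec$samples, p = target_fs / g, q = rec$fs / g)
  n_out <- round(length(rec$samples) * target_fs / rec$fs)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
  pcg_recording(y, target_fs, rec$record_id, rec$label)
}

rational_gcd <- function(a, b) {
  a <- round(a); b <- round(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Peak-normalize a recording
#'
#' Scales the waveform so that `max(abs(samples)) == 1`; shape (and sign)
#' preserved. All-zero signals are rejected.
#'
#' @param rec A [pcg_recording()].
#' @return The normalized recording.
#' @export
peak_normalize <- function(rec) {
  stopifnot(inherits(rec, "pcg_recording"))
  peak <- max(abs(rec$samples))
  if (peak == 0)
    stop(pcg_error("pcg_zero_signal", sprintf("all-zero signal: %s", rec$record_id)))
  rec$samples <- rec$samples / peak
  rec
}

## ---- manifests ------------------------------------------------------------

#' Build a label manifest
#'
#' @param record_id Character vector of unique identifiers.
#' @param path File paths (may be `NA` for in-memory corpora).
#' @param label Labels in the three-class vocabulary (`normal`, `murmur`,
#'   `extrasystole`) or the binarized one (`normal`, `abnormal`).
#' @return A `data.frame` of class `pcg_manifest` with columns
#'   `record_id`, `path`, `label`.
#' @export
pcg_manifest <- function(record_id, path = NA_character_, label) {
  record_id <- as.character(record_id)
  label <- as.character(label)
  if (anyDuplicated(record_id))
    stop(pcg_error("pcg_manifest_dup", "record_ids must be unique"))
  bad <- setdiff(unique(label), c("normal", "murmur", "extrasystole", "abnormal"))
  if (length(bad))
    stop(pcg_error("pcg_bad_label", sprintf("unknown label(s): %s", paste(bad, collapse = ", "))))
  out <- data.frame(record_id = record_id,
                    path = rep_len(as.character(path), length(record_id)),
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("pcg_manifest", "data.frame")
  out
}

#' Read a manifest CSV (`record_id,path,label`)
#'
#' Relative `path` entries are resolved against the CSV's directory.
#'
#' @param file CSV path.
#' @return A [pcg_manifest()].
#' @export
read_manifest <- function(file) {
  if (!file.exists(file))
    stop(pcg_error("pcg_missing_file", sprintf("manifest not found: %s", file)))
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("record_id", "path", "label")
  if (!all(need %in% names(df)))
    stop(pcg_error("pcg_bad_manifest", "manifest must have columns record_id,path,label"))
  rel <- !is.na(df$path) & !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(file), df$path[rel])
  pcg_manifest(df$record_id, df$path, df$label)
}

#' Write a manifest CSV
#' @param man A [pcg_manifest()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_manifest <- function(man, file) {
  utils::write.csv(as.data.frame(man)[c("record_id", "path", "label")], file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Class counts of a manifest
#' @param man A [pcg_manifest()].
#' @return Named integer vector of per-label counts.
#' @export
class_counts <- function(man) {
  tab <- table(man$label)
  stats::setNames(as.integer(tab), names(tab))
}

#' Binarize manifest labels
#'
#' Maps `murmur` and `extrasystole` to `abnormal`; `normal` is kept. The
#' entry count is unchanged.
#'
#' @param man A [pcg_manifest()] with three-class labels.
#' @return The binarized manifest.
#' @export
binarize_labels <- function(man) {
  bad <- setdiff(unique(man$label), c("normal", "murmur", "extrasystole"))
  if (length(bad))
    stop(pcg_error("pcg_bad_label", sprintf("cannot binarize label(s): %s", paste(bad, collapse = ", "))))
  man$label[man$label %in% c("murmur", "extrasystole")] <- "abnormal"
  man
}

#' Balance classes by undersampling the majority class
#'
#' The majority class is undersampled without replacement down to the
#' minority count under a fixed seed; the minority class is untouched.
#' Retained rows keep their original manifest order.
#'
#' @param man A binarized [pcg_manifest()] with both classes present.
#' @param seed Integer seed controlling the undersampling draw.
#' @return The balanced manifest.
#' @export
balance_classes <- function(man, seed = 42) {
  counts <- class_counts(man)
  if (length(counts) < 2L || any(counts == 0L))
    stop(pcg_error("pcg_empty_class", "both classes must be present to balance"))
  n_min <- min(counts)
  keep <- logical(nrow(man))
  with_seed(seed, {
    for (lb in names(counts)) {
      idx <- which(man$label == lb)
      if (length(idx) > n_min) idx <- sort(sample(idx, n_min))
      keep[idx] <- TRUE
    }
  })
  out <- man[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
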