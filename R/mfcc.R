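#' Framing configuration for short-time analysis
#'
#' Defaults follow the pipeline's standard setting: 25-ms frames with a
#' 10-ms step (60% overlap), which yields 298 frames for a 3-s segment at
#' 4000 Hz, and a 128-point FFT (next power of two above the 100-sample
#' frame).
#'
#' @param frame_s Frame length in seconds.
#' @param step_s Hop between frame starts in seconds.
#' @param n_fft FFT length in samples (`NULL` = next power of two at or above
#'   the frame length).
#' @return A list of class `framing_config`.
#' @export
framing_config <- function(frame_s = 0.025, step_s = 0.010, n_fft = NULL) {
  if (!(step_s > 0 && step_s <= frame_s))
    stop(pcg_error("pcg_bad_framing", "need 0 < step_s <= frame_s"))
  structure(list(frame_s = frame_s, step_s = step_s, n_fft = n_fft),
            class = "framing_config")
}

#' Triangular (Bartlett) window
#'
#' Piecewise-linear weights `w(n) = 2n/N` for `0 <= n <= N/2` and
#' `2 - 2n/N` for `N/2 <= n <= N`, evaluated at the integers `n = 0..N`
#' (length `N + 1`). Endpoints are 0 and the midpoint is 1.
#'
#' @param N Window order (`N >= 2`); the window has `N + 1` points.
#' @return Numeric vector of weights.
#' @export
bartlett_window <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N < 2)
    stop(pcg_error("pcg_bad_window", "N must be >= 2"))
  n <- 0:N
  ifelse(n <= N / 2, 2 * n / N, 2 - 2 * n / N)
}

#' Slice a recording into windowed frames
#'
#' The signal is cut into frames of `round(frame_s * fs)` samples advancing
#' by `round(step_s * fs)` samples; each frame is multiplied elementwise by a
#' Bartlett window. The frame count is
#' `floor((L - frame_len) / hop) + 1`.
#'
#' @param rec A [pcg_recording()].
#' @param cfg A [framing_config()].
#' @return A list of class `pcg_frames` with the windowed frame matrix
#'   (`n_frames x frame_len`), the window, and the framing geometry.
#' @export
frame_signal <- function(rec, cfg = framing_config()) {
  stopifnot(inherits(rec, "pcg_recording"), inherits(cfg, "framing_config"))
  x <- rec$samples
  frame_len <- round(cfg$frame_s * rec$fs)
  hop <- round(cfg$step_s * rec$fs)
  if (length(x) < frame_len)
    stop(pcg_error("pcg_signal_too_short", "signal shorter than one frame"))
  n_frames <- (length(x) - frame_len) %/% hop + 1L
  w <- bartlett_window(frame_len - 1L)
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(starts, seq_len(frame_len), `+`)
  frames <- matrix(x[idx], nrow = n_frames) * rep(w, each = n_frames)
  structure(list(frames = frames, window = w, frame_len = frame_len,
                 hop = hop, fs = rec$fs),
            class = "pcg_frames")
}

#' One-sided magnitude spectra of windowed frames
#'
#' Frames are zero-padded to `n_fft` samples and transformed with the FFT;
#' magnitudes are returned for bins `k = 0..n_fft/2`.
#'
#' @param fr A [frame_signal()] result.
#' @param n_fft FFT length (at or above the frame length).
#' @return Matrix `n_frames x (n_fft/2 + 1)` of `|X[k]|`.
#' @export
magnitude_spectrum <- function(fr, n_fft = NULL) {
  stopifnot(inherits(fr, "pcg_frames"))
  if (is.null(n_fft)) n_fft <- next_pow2(fr$frame_len)
  if (n_fft < fr$frame_len)
    stop(pcg_error("pcg_bad_fft", "n_fft must be >= frame length"))
  padded <- matrix(0, nrow = n_fft, ncol = nrow(fr$frames))
  padded[seq_len(fr$frame_len), ] <- t(fr$frames)
  spec <- stats::mvfft(padded)
  t(Mod(spec[seq_len(n_fft %/% 2 + 1L), , drop = FALSE]))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Hertz to mel conversion
#'
#' `m = 2595 * log10(1 + f/700)`, the standard perceptual frequency warping.
#'
#' @param f Frequency in Hz (non-negative).
#' @return Mel value(s).
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop(pcg_error("pcg_bad_freq", "frequency must be non-negative"))
  2595 * log10(1 + f / 700)
}

#' Mel to Hertz conversion (inverse of [hz_to_mel()])
#' @param m Mel value(s).
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filter bank
#'
#' `n_filters + 2` edge frequencies are spaced equally on the mel axis
#' between `fmin` and `fmax` and mapped to FFT bin indices
#' `floor((n_fft + 1) * f / fs)`. Filter `m` rises linearly from edge
#' `m - 1` to its center at edge `m` (peak weight 1) and falls to edge
#' `m + 1`; it is zero elsewhere.
#'
#' @param n_filters Number of triangular filters (default 20).
#' @param n_fft FFT length the bank applies to.
#' @param fs Sampling rate in Hz.
#' @param fmin,fmax Frequency range in Hz (`fmax <= fs/2`).
#' @return A list of class `mel_filterbank` with the weight matrix `B`
#'   (`n_filters x (n_fft/2 + 1)`), center frequencies and edges.
#' @export
mel_filterbank <- function(n_filters = 20, n_fft = 128, fs = 4000,
                           fmin = 0, fmax = fs / 2) {
  stopifnot(n_filters >= 1, fmax <= fs / 2, fmin >= 0, fmin < fmax)
  edges_mel <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2L)
  edges_hz <- mel_to_hz(edges_mel)
  bins <- floor((n_fft + 1) * edges_hz / fs)
  if (anyDuplicated(bins[2:(n_filters + 1L)]))
    stop(pcg_error("pcg_filterbank_resolution",
                   "duplicate filter center bins: n_filters too large for this n_fft"))
  n_bins <- n_fft %/% 2 + 1L
  B <- matrix(0, nrow = n_filters, ncol = n_bins)
  k <- 0:(n_bins - 1L)
  for (m in seq_len(n_filters)) {
    lo <- bins[m]; cen <- bins[m + 1L]; hi <- bins[m + 2L]
    up <- k >= lo & k <= cen
    dn <- k >= cen & k <= hi
    if (cen > lo) B[m, up] <- (k[up] - lo) / (cen - lo)
    if (hi > cen) B[m, dn] <- (hi - k[dn]) / (hi - cen)
    B[m, k == cen] <- 1
  }
  structure(list(B = B, centers_hz = edges_hz[2:(n_filters + 1L)],
                 edges_hz = edges_hz, bins = bins, n_fft = n_fft, fs = fs),
            class = "mel_filterbank")
}

#' Log mel-band energies
#'
#' Per frame and filter, the filter-weighted sum of the power spectrum,
#' `E_m = sum_k |X[k]|^2 B(m, k)`, followed by a natural log with an energy
#' floor: `Elog = log(max(E_m, floor))`.
#'
#' @param spectra One-sided magnitude spectra (from [magnitude_spectrum()]).
#' @param bank A [mel_filterbank()] built for the same `n_fft`.
#' @param floor_energy Energy floor applied before the log.
#' @return Matrix `n_frames x n_filters` of log energies (all finite).
#' @export
mel_log_energies <- function(spectra, bank, floor_energy = 1e-10) {
  stopifnot(inherits(bank, "mel_filterbank"))
  if (ncol(spectra) != ncol(bank$B))
    stop(pcg_error("pcg_shape_mismatch", "spectra bins do not match filter bank bins"))
  Em <- (spectra^2) %*% t(bank$B)
  log(pmax(Em, floor_energy))
}

#' Cepstral coefficients by discrete cosine transform
#'
#' Per frame, coefficient `n` is
#' `sum_{m=1..M} Elog(m) * cos(n (m - 1/2) pi / M)` for `n = 1..n_mfcc`
#' (the 0th, overall-energy coefficient is excluded).
#'
#' @param Elog Log mel-energy matrix (`n_frames x M`).
#' @param n_mfcc Number of cepstral coefficients to keep (`<= M`).
#' @return Matrix `n_frames x n_mfcc` of MFCCs.
#' @export
dct_cepstra <- function(Elog, n_mfcc) {
  Elog <- as.matrix(Elog)
  M <- ncol(Elog)
  if (n_mfcc > M)
    stop(pcg_error("pcg_bad_ncoef", "n_mfcc must not exceed the filter count"))
  m <- seq_len(M)
  cosmat <- sapply(seq_len(n_mfcc), function(n) cos(n * (m - 0.5) * pi / M))
  C <- Elog %*% cosmat
  colnames(C) <- sprintf("mfcc%02d", seq_len(n_mfcc))
  C
}

#' Per-recording MFCC summary features
#'
#' Runs the full cepstral chain (framing, Bartlett windowing, FFT, mel
#' filter bank, log compression, DCT) and summarizes each coefficient by its
#' mean and population standard deviation across frames. The filter count is
#' `max(20, n_mfcc)` so that up to 26 independent coefficients can be taken.
#'
#' @param rec A recording standardized to the analysis duration (3 s).
#' @param n_mfcc Number of cepstral coefficients (8, 12, 16, 20 or 26).
#' @param cfg A [framing_config()].
#' @return Named numeric vector of `2 * n_mfcc` features
#'   (`mfcc01_mean`, `mfcc01_std`, ...).
#' @export
mfcc_features <- function(rec, n_mfcc = 20, cfg = framing_config()) {
  fr <- frame_signal(rec, cfg)
  n_fft <- if (is.null(cfg$n_fft)) next_pow2(fr$frame_len) else cfg$n_fft
  spec <- magnitude_spectrum(fr, n_fft)
  bank <- mel_filterbank(n_filters = max(20L, n_mfcc), n_fft = n_fft, fs = rec$fs)
  C <- dct_cepstra(mel_log_energies(spec, bank), n_mfcc)
  mu <- colMeans(C)
  sdev <- sqrt(colMeans(C^2) - mu^2)  # population standard deviation
  sdev[sdev < 0 | is.nan(sdev)] <- 0
  out <- as.numeric(rbind(mu, sdev))
  names(out) <- as.vector(rbind(paste0(colnames(C), "_mean"),
                                paste0(colnames(C), "_std")))
  out
}
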