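#' Synthetic phonocardiogram generator configuration
#'
#' The generator emulates the acoustic structure the pipeline assumes:
#' ~0.8-s cardiac cycles carrying two transient low-frequency damped
#' oscillations (S1 at the cycle start, S2 at 30% of the cycle), murmurs as
#' band-limited 125-500 Hz noise filling the S1-S2 systolic interval, and
#' extrasystoles as premature cycles (50-70% length, S1-like burst only)
#' followed by a compensatory pause. All randomness derives from one seed.
#'
#' @param fs Sampling rate in Hz.
#' @param cycle_s Nominal cardiac-cycle duration in seconds.
#' @param duration_s Recording duration in seconds (may be below or above
#'   the 3-s analysis window to exercise trimming/extension).
#' @param s1_freq,s2_freq Carrier frequency ranges (Hz) of the S1/S2 damped
#'   sinusoids; one value per recording is drawn from each range.
#' @param murmur_band Murmur noise band in Hz (targets wavelet subbands
#'   D3/D4 at 4000 Hz).
#' @param murmur_snr_db Murmur-to-heart-sound RMS ratio in dB; `-Inf`
#'   silences the murmur exactly.
#' @param extrasystole_prob Per-cycle probability of a premature beat (at
#'   least one is always inserted when positive).
#' @param noise_sd Standard deviation of the additive background noise.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs = 4000, cycle_s = 0.8, duration_s = 3,
                         s1_freq = c(60, 100), s2_freq = c(80, 150),
                         murmur_band = c(125, 500), murmur_snr_db = 6,
                         extrasystole_prob = 0.4, noise_sd = 0.01) {
  stopifnot(fs > 0, duration_s > 0, cycle_s > 0,
            max(s1_freq, s2_freq, murmur_band) < fs / 2)
  structure(list(fs = fs, cycle_s = cycle_s, duration_s = duration_s,
                 s1_freq = s1_freq, s2_freq = s2_freq,
                 murmur_band = murmur_band, murmur_snr_db = murmur_snr_db,
                 extrasystole_prob = extrasystole_prob, noise_sd = noise_sd),
            class = "synth_config")
}

## Exponentially damped sinusoid with a 5-ms linear attack.
.pcg_burst <- function(freq, dur_s, tau, fs) {
  t <- seq(0, dur_s, by = 1 / fs)
  env <- exp(-t / tau)
  attack <- pmin(t / 0.005, 1)
  sin(2 * pi * freq * t) * env * attack
}

## Core generator. The same random draws are made for every class (jitter,
## premature-beat variables, murmur noise), and class only changes how they
## are applied, so recordings of different classes with the same seed share
## their underlying normal template.
.synth_pcg <- function(cfg, seed, class) {
  fs <- cfg$fs
  n_target <- round(cfg$duration_s * fs)
  bp <- signal::butter(2, cfg$murmur_band / (fs / 2), type = "pass")
  gain_db <- if (class == "murmur") cfg$murmur_snr_db else -Inf
  premature_on <- class == "extrasystole" && cfg$extrasystole_prob > 0

  x <- numeric(0)
  with_seed(seed, {
    f1 <- stats::runif(1, cfg$s1_freq[1], cfg$s1_freq[2])
    f2 <- stats::runif(1, cfg$s2_freq[1], cfg$s2_freq[2])
    k <- 0L
    premature_seen <- FALSE
    while (length(x) < n_target) {
      k <- k + 1L
      jitter <- stats::runif(1, 0.98, 1.02)
      u_prem <- stats::runif(1)
      ratio <- stats::runif(1, 0.5, 0.7)
      n_c <- round(cfg$cycle_s * jitter * fs)
      s1 <- .pcg_burst(f1, 0.12, 0.03, fs)
      s2 <- 0.75 * .pcg_burst(f2, 0.09, 0.022, fs)
      # murmur noise spans the S1->S2 systolic interval
      m_lo <- round(0.15 * n_c); m_hi <- round(0.30 * n_c)
      mnoise <- as.numeric(signal::filter(bp, stats::rnorm(m_hi - m_lo + 1L)))

      is_premature <- premature_on &&
        (u_prem < cfg$extrasystole_prob ||
           (!premature_seen && (length(x) + 2L * n_c) >= n_target))
      if (is_premature) premature_seen <- TRUE

      if (is_premature) {
        # short premature cycle with an S1-like burst, then a compensatory
        # pause: premature + pause together span two nominal cycles
        n_short <- round(ratio * n_c)
        cyc <- numeric(n_short + round((2 - ratio) * n_c))
        cyc[seq_along(s1)] <- 0.9 * s1
        at <- n_short + 1L
        cyc[at:(at + length(s1) - 1L)] <- cyc[at:(at + length(s1) - 1L)] + s1
        at2 <- n_short + round(0.3 * n_c) + 1L
        cyc[at2:(at2 + length(s2) - 1L)] <- cyc[at2:(at2 + length(s2) - 1L)] + s2
      } else {
        cyc <- numeric(n_c)
        cyc[seq_along(s1)] <- s1
        at2 <- round(0.3 * n_c) + 1L
        cyc[at2:(at2 + length(s2) - 1L)] <- cyc[at2:(at2 + length(s2) - 1L)] + s2
        gain <- 10^(gain_db / 20)
        if (gain > 0) {
          ref <- sqrt(mean(s1^2))
          mn <- mnoise / max(sqrt(mean(mnoise^2)), 1e-12) * gain * ref
          # soft edges on the murmur window
          ramp <- pmin(seq_along(mn) / (0.1 * length(mn)),
                       rev(seq_along(mn)) / (0.1 * length(mn)), 1)
          cyc[m_lo:m_hi] <- cyc[m_lo:m_hi] + mn * ramp
        }
      }
      x <- c(x, cyc)
    }
    x <- x[seq_len(n_target)]
    x <- x + stats::rnorm(n_target, sd = cfg$noise_sd)
  })
  pcg_recording(0.9 * x / max(abs(x)), fs,
                record_id = sprintf("%s_%d", class, seed), label = class)
}

#' Synthesize a normal heart-sound recording
#'
#' Regular ~0.8-s cycles, each with an S1 burst at the cycle start and an S2
#' burst at 30% of the cycle, plus low-level background noise.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed; the waveform is a deterministic function of it.
#' @return A labeled [pcg_recording()].
#' @export
synth_normal <- function(cfg = synth_config(), seed = 1L) {
  .synth_pcg(cfg, seed, "normal")
}

#' Synthesize a murmur recording
#'
#' The normal template for the same seed plus band-limited (125-500 Hz)
#' noise filling each systolic S1-S2 interval at the configured
#' murmur-to-heart-sound ratio; `murmur_snr_db = -Inf` reproduces the
#' normal template exactly.
#'
#' @inheritParams synth_normal
#' @return A labeled [pcg_recording()].
#' @export
synth_murmur <- function(cfg = synth_config(), seed = 1L) {
  .synth_pcg(cfg, seed, "murmur")
}

#' Synthesize an extrasystole recording
#'
#' At least one cycle is replaced by a premature beat: a 50-70%-length cycle
#' holding an S1-like burst, followed by a compensatory pause (the premature
#' beat and pause together span two nominal cycles), which disrupts the
#' regular inter-S1 interval.
#'
#' @inheritParams synth_normal
#' @return A labeled [pcg_recording()].
#' @export
synth_extrasystole <- function(cfg = synth_config(), seed = 1L) {
  if (cfg$extrasystole_prob <= 0)
    warning("extrasystole_prob is 0; output reduces to the normal template")
  .synth_pcg(cfg, seed, "extrasystole")
}

#' Generate a labeled synthetic corpus on disk
#'
#' Writes WAV files and a manifest CSV (`record_id,path,label`). A fraction
#' of abnormal recordings is generated shorter than 3 s to exercise the
#' cycle-duplication extension; all others are longer than 3 s to exercise
#' trimming. Regeneration with the same seed is byte-identical.
#'
#' @param n_per_class Recordings per class: a single count or a named vector
#'   with entries `normal`, `murmur`, `extrasystole`.
#' @param out_dir Output directory (created if needed).
#' @param cfg A [synth_config()] (its `duration_s` is overridden per
#'   recording).
#' @param seed Master integer seed.
#' @param short_fraction Fraction of each abnormal class generated shorter
#'   than 3 s.
#' @return The corpus [pcg_manifest()] (with a `manifest.csv` alongside the
#'   WAVs).
#' @export
make_corpus <- function(n_per_class, out_dir, cfg = synth_config(), seed = 42L,
                        short_fraction = 0.1) {
  classes <- c("normal", "murmur", "extrasystole")
  if (length(n_per_class) == 1L && is.null(names(n_per_class)))
    n_per_class <- stats::setNames(rep(n_per_class, 3L), classes)
  stopifnot(all(classes %in% names(n_per_class)), all(n_per_class >= 1L))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop(pcg_error("pcg_unwritable_dir", sprintf("cannot create directory: %s", out_dir)))
  gens <- list(normal = synth_normal, murmur = synth_murmur,
               extrasystole = synth_extrasystole)
  ids <- character(0); paths <- character(0); labels <- character(0)
  k <- 0L
  for (cls in classes) {
    n_short <- if (cls == "normal") 0L else ceiling(short_fraction * n_per_class[[cls]])
    for (j in seq_len(n_per_class[[cls]])) {
      k <- k + 1L
      rec_seed <- as.integer((as.numeric(seed) * 100003 + k * 17) %% 2147483646) + 1L
      dur <- with_seed(rec_seed, {
        u <- stats::runif(1)
        if (j <= n_short) 1.5 + 1.3 * u else 3.2 + 2.8 * u
      })
      cfg_j <- cfg; cfg_j$duration_s <- dur
      rec <- gens[[cls]](cfg_j, seed = rec_seed + 1L)
      rec$record_id <- sprintf("%s_%03d", cls, j)
      path <- file.path(out_dir, paste0(rec$record_id, ".wav"))
      write_wav(rec, path)
      ids <- c(ids, rec$record_id); paths <- c(paths, path); labels <- c(labels, cls)
    }
  }
  man <- pcg_manifest(ids, paths, labels)
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  man
}
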