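## Orthonormal Daubechies scaling (low-pass) filters with N vanishing
## moments and 2N taps, from the standard published coefficient tables.
## sum(h) = sqrt(2), sum(h^2) = 1, double-shift orthogonal.
.db_lowpass <- list(
  db4 = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.032883011666885197, -0.010597401785069032),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.75113390802109536,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.097501605587323043, 0.027522865530305727, -0.03158203931748603,
          0.00055384220116149613, 0.0047772575109455108, -0.0010773010853084796),
  db8 = c(0.054415842243104008, 0.31287159091429995, 0.67563073629728976,
          0.58535468365420673, -0.015829105256349306, -0.28401554296154691,
          0.00047248457391328279, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.0087460940474057766,
          -0.0048703529934515741, -0.00039174037337694705,
          0.00067544940645056933, -0.00011747678412476953))

#' Daubechies wavelet filter pair
#'
#' Returns the orthonormal Daubechies scaling (low-pass) filter `h` with
#' `order` vanishing moments (filter length `2 * order`) and its quadrature
#' mirror high-pass `g[n] = (-1)^n h[L - 1 - n]`.
#'
#' @param order Number of vanishing moments: 4, 6 or 8.
#' @return A list of class `wavelet_family` with elements `name`, `h`, `g`,
#'   `length`.
#' @export
daubechies_filters <- function(order) {
  name <- paste0("db", order)
  if (!name %in% names(.db_lowpass))
    stop(pcg_error("pcg_bad_wavelet", "supported Daubechies orders: 4, 6, 8"))
  h <- .db_lowpass[[name]]
  L <- length(h)
  g <- (-1)^(0:(L - 1L)) * rev(h)
  structure(list(name = name, h = h, g = g, length = L), class = "wavelet_family")
}

## One periodized analysis step: y_low[k] = sum_m h[m] x[(2k + m) mod N].
.dwt_step <- function(x, fam) {
  N <- length(x)
  half <- N %/% 2L
  idx <- outer(2L * (0:(half - 1L)), 0:(fam$length - 1L), `+`) %% N + 1L
  xm <- matrix(x[idx], nrow = half)
  list(A = drop(xm %*% fam$h), D = drop(xm %*% fam$g))
}

## Inverse of .dwt_step (transpose of the orthogonal analysis operator).
.idwt_step <- function(A, D, fam) {
  N <- 2L * length(A)
  x <- numeric(N)
  for (k in seq_along(A)) {
    contrib <- A[k] * fam$h + D[k] * fam$g
    for (m in seq_len(fam$length)) {
      # scalar accumulation: when the filter wraps (N < filter length) the
      # same position can occur more than once per shift
      pos <- (2L * (k - 1L) + m - 1L) %% N + 1L
      x[pos] <- x[pos] + contrib[m]
    }
  }
  x
}

#' Multilevel discrete wavelet decomposition
#'
#' Cascaded filter-and-downsample-by-two analysis with periodic boundary
#' extension, giving detail subbands `D1..Dlevels` and the final
#' approximation. With periodic extension the transform is orthogonal:
#' subband energies sum exactly to the signal energy. Signals whose length
#' is not divisible by `2^levels` are zero-padded up to the next multiple
#' (zero samples add no energy).
#'
#' @param x Numeric signal (or a [pcg_recording()]).
#' @param family A [daubechies_filters()] pair or an order (4, 6, 8).
#' @param levels Number of decomposition levels.
#' @param fs Sampling rate used only to annotate nominal band edges.
#' @return A list of class `pcg_subbands`: coefficient vectors `D1..D4`,
#'   `A4` (for `levels = 4`), the family name, and `band_hz` (the nominal
#'   frequency ranges, halving per level).
#' @export
dwt_multilevel <- function(x, family = daubechies_filters(4), levels = 4, fs = 4000) {
  if (inherits(x, "pcg_recording")) { fs <- x$fs; x <- x$samples }
  if (is.numeric(family)) family <- daubechies_filters(family)
  stopifnot(inherits(family, "wavelet_family"))
  if (length(x) < 2^levels)
    stop(pcg_error("pcg_signal_too_short", "signal too short for requested levels"))
  block <- 2^levels
  if (length(x) %% block != 0L)
    x <- c(x, numeric(block - length(x) %% block))
  out <- list()
  cur <- x
  for (j in seq_len(levels)) {
    st <- .dwt_step(cur, family)
    out[[paste0("D", j)]] <- st$D
    cur <- st$A
  }
  out[[paste0("A", levels)]] <- cur
  structure(c(out, list(family = family$name, fs = fs,
                        band_hz = subband_bands(fs, levels))),
            class = "pcg_subbands")
}

#' Inverse multilevel wavelet transform
#'
#' Reconstructs the (possibly zero-padded) signal from a [dwt_multilevel()]
#' decomposition; with periodic extension the reconstruction is exact.
#'
#' @param sb A `pcg_subbands` object.
#' @return Numeric signal.
#' @export
idwt_multilevel <- function(sb) {
  stopifnot(inherits(sb, "pcg_subbands"))
  fam <- daubechies_filters(as.integer(sub("db", "", sb$family)))
  levels <- sum(grepl("^D[0-9]+$", names(sb)))
  cur <- sb[[paste0("A", levels)]]
  for (j in rev(seq_len(levels)))
    cur <- .idwt_step(cur, sb[[paste0("D", j)]], fam)
  cur
}

#' Nominal subband frequency ranges
#'
#' Each decomposition level halves the bandwidth: detail `Dj` nominally
#' covers `fs / 2^(j+1)` to `fs / 2^j` Hz and the final approximation covers
#' `0` to `fs / 2^(levels+1)` Hz (at 4000 Hz: D1 1000-2000, D2 500-1000,
#' D3 250-500, D4 125-250, A4 0-125).
#'
#' @param fs Sampling rate in Hz.
#' @param levels Number of levels.
#' @return Data frame with columns `subband`, `low_hz`, `high_hz`.
#' @export
subband_bands <- function(fs = 4000, levels = 4) {
  j <- seq_len(levels)
  data.frame(subband = c(paste0("D", j), paste0("A", levels)),
             low_hz = c(fs / 2^(j + 1), 0),
             high_hz = c(fs / 2^j, fs / 2^(levels + 1)),
             stringsAsFactors = FALSE)
}

#' Six statistical descriptors of a coefficient sequence
#'
#' Mean, population standard deviation, variance (`std^2`), energy
#' (`sum(c^2)`), Shannon energy `-sum(ct^2 * ln(ct^2))` with
#' `ct = c / max(abs(c))` and the `0 * log 0 = 0` convention, and Shannon
#' entropy `-sum(p * log2(p))` over the energy distribution
#' `p = c^2 / sum(c^2)`. An all-zero input yields all six equal to 0.
#'
#' @param coeffs Non-empty numeric vector.
#' @return Named numeric vector: `mean`, `std`, `variance`, `energy`,
#'   `shannon_energy`, `shannon_entropy`.
#' @export
subband_stats <- function(coeffs) {
  if (length(coeffs) == 0L)
    stop(pcg_error("pcg_empty_subband", "empty coefficient sequence"))
  mu <- mean(coeffs)
  v <- mean(coeffs^2) - mu^2
  v <- max(v, 0)
  energy <- sum(coeffs^2)
  if (energy == 0) {
    se <- 0; ent <- 0; mu <- 0; v <- 0
  } else {
    ct2 <- (coeffs / max(abs(coeffs)))^2
    nz <- ct2 > 0
    se <- -sum(ct2[nz] * log(ct2[nz]))
    p <- coeffs^2 / energy
    nzp <- p > 0
    ent <- -sum(p[nzp] * log2(p[nzp]))
  }
  c(mean = mu, std = sqrt(v), variance = v, energy = energy,
    shannon_energy = se, shannon_entropy = ent)
}

#' Per-recording wavelet summary features
#'
#' Four-level Daubechies decomposition followed by the six statistical
#' descriptors of each of the five subbands (D1-D4, A4): 30 named features.
#' Feature names and order are identical across wavelet families.
#'
#' @param rec A recording standardized to the analysis duration.
#' @param family A [daubechies_filters()] pair or an order (4, 6, 8).
#' @param levels Number of decomposition levels.
#' @return Named numeric vector of `5 * 6 = 30` features
#'   (`d1_mean`, ..., `a4_shannon_entropy`).
#' @export
wavelet_features <- function(rec, family = daubechies_filters(4), levels = 4) {
  sb <- dwt_multilevel(rec, family = family, levels = levels)
  bands <- c(paste0("D", seq_len(levels)), paste0("A", levels))
  out <- unlist(lapply(bands, function(b) {
    st <- subband_stats(sb[[b]])
    stats::setNames(st, paste0(tolower(b), "_", names(st)))
  }))
  out
}
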