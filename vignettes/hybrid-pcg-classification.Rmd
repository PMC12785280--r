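---
title: "Hybrid MFCC-wavelet classification of heart sounds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid MFCC-wavelet classification of heart sounds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgclass)
```

## The problem and the model

Phonocardiogram (PCG) recordings are short, non-stationary acoustic signals:
each ~0.8-s cardiac cycle carries two transient low-frequency events — S1
(atrioventricular valve closure) and S2 (semilunar valve closure) — while
pathology shows up either as extra spectral content (murmurs from turbulent
flow, broadband and systolic) or as rhythm disruption (extrasystoles,
premature beats with a compensatory pause). `pcgclass` implements a
classical, fully interpretable pipeline for deciding *normal* vs *abnormal*
from a single recording:

1. **Standardization.** Audio is resampled to 4000 Hz, peak-normalized to
   unit maximum amplitude, and cut to exactly 3.0 s. Recordings longer than
   3 s keep their first 3 s; shorter ones are extended by appending verbatim
   copies of the recording's initial cardiac cycle (0.8 s chunks, the last
   chunk truncated). Three seconds covers roughly four cardiac cycles, so
   rhythm-level pathology is observable.
2. **Hybrid features.** Two complementary views are concatenated per
   recording:
   * *Cepstral:* 25-ms Bartlett-windowed frames with a 10-ms hop (60%
     overlap, 298 frames per segment), 128-point FFT, a bank of triangular
     filters equally spaced on the mel scale
     $m = 2595\log_{10}(1+f/700)$, log filterbank energies
     $E^{\log}_m = \log \sum_k |X[k]|^2 B(m,k)$, and the cosine transform
     $c_n = \sum_{m=1}^{M} E^{\log}_m \cos\!\big(n(m-\tfrac12)\pi/M\big)$,
     $n = 1..n_\mathrm{mfcc}$. Each coefficient is summarized by its mean
     and population standard deviation across frames
     ($2 n_\mathrm{mfcc}$ features).
   * *Wavelet:* a 4-level Daubechies DWT (db4/db6/db8, periodic boundary)
     splits the band into D1 (1000–2000 Hz), D2 (500–1000), D3 (250–500),
     D4 (125–250) and A4 (0–125) at 4000 Hz; each subband is summarized by
     mean, population SD, variance, energy $\sum c^2$, Shannon energy
     $-\sum \tilde c^2 \ln \tilde c^2$ (amplitude-normalized
     $\tilde c = c/\max|c|$), and Shannon entropy $-\sum p \log_2 p$ over
     the energy distribution $p = c^2/\sum c^2$ (30 features).

   Crossing $n_\mathrm{mfcc} \in \{8, 12, 16, 20, 26\}$ with the three
   wavelet families yields 15 hybrid datasets of $2n_\mathrm{mfcc}+30 \in
   \{46, \dots, 82\}$ features.
3. **Leakage-free evaluation.** A stratified 80/20 split is drawn once per
   experiment. Z-score standardization is fitted on training rows only;
   feature selection (greedy forward selection and a Boruta-style shadow
   procedure) sees training rows only; hyperparameters of the four
   classifiers (RBF SVM, L2 logistic regression, decision tree, random
   forest) are grid-searched with stratified 5-fold CV inside the training
   split; metrics (accuracy, precision, recall, specificity, F1, ROC/AUC
   with abnormal as the positive class) come from the held-out 20%. The
   full plan is 15 datasets × 2 selectors × 4 classifiers = 120 models.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| target duration | 3.0 | s | ≈ 4 cardiac cycles; pathology is not always visible in one cycle |
| cycle length | 0.8 | s | physiological average; also the extension chunk size |
| sampling rate | 4000 | Hz | wavelet band edges presuppose it; Nyquist 2 kHz covers heart sounds |
| frame / hop | 25 / 10 | ms | captures transient S1/S2; 60% overlap, 298 frames per segment |
| FFT length | 128 | samples | next power of two above the 100-sample frame; zero-padded |
| mel filters | max(20, n_mfcc) | – | 20 filters standard; raised to 26 when 26 coefficients are requested so the cosine transform has full rank |
| mel range | 0–2000 | Hz | full band at fs = 4000 |
| energy floor | 1e-10 | – | keeps the log finite on silent frames |
| DWT levels | 4 | – | produces the D1–D4/A4 band map above |
| forward sizes | 5–25 step 5 | features | evaluated on one greedy path; best CV size wins, ties to the smaller |
| Boruta | 100 iter, alpha 0.05 | – | shadow-max hits, binomial tests, two-step FDR + per-iteration Bonferroni |
| test fraction | 0.2 | – | 45 of 224 rows, per-class largest-remainder rounding (23 normal / 22 abnormal) |
| master seed | 42 | – | drives split, folds, forests, and generator draws |

## Numerical and design choices

* **Trimming is start-anchored.** Both trimming and extension reuse the
  *initial* segment of the recording, so the first `min(len, 12000)`
  samples of any output always equal the input prefix, extension is
  idempotent, and no synthesized or crossfaded material is introduced. No
  S1 detection is attempted to align the copied cycle; the chunk starts at
  sample 0.
* **The cepstral transform is applied literally**, with coefficients
  indexed $n = 1..n_\mathrm{mfcc}$ (the 0th, overall-loudness coefficient
  is excluded, which makes the features invariant to amplitude scaling). A
  consequence of the literal indexing: at $n = M$ the cosine weights
  $\cos(M(m-\tfrac12)\pi/M)$ vanish identically, so the last coefficient of
  the $n_\mathrm{mfcc} = 20$ and $26$ configurations is exactly zero. Those
  columns are constant, are standardized to zero (with a logged warning)
  rather than erroring, and carry no selectable signal.
* **Filter-count rule.** Twenty mel filters cannot yield 26 independent
  cosine coefficients, so the bank is enlarged to $M = \max(20,
  n_\mathrm{mfcc})$ equally-spaced-in-mel filters. This preserves
  coefficient independence up to the structural zero above.
* **Periodic wavelet boundary.** Periodization makes the DWT an exactly
  orthogonal transform (subband energies sum to the signal energy;
  inversion is exact to rounding), which the tests exploit by building the
  32×32 transform matrix explicitly. Signals whose length is not divisible
  by $2^{levels}$ are zero-padded — zero samples add no energy. "Daubechies
  N" is read as the family with N vanishing moments and 2N taps (db4 = 8
  taps).
* **Population (÷N) standard deviations** everywhere (frame statistics,
  subband statistics, z-scoring), so a z-scored training column has
  population SD exactly 1. Constant training columns transform to zero with
  a warning — degenerate inputs must not crash a 120-model run.
* **Subband "energy" is the raw sum of squares**, not the mean square; the
  Shannon descriptors use the conventions standard in PCG work, with
  $0\log 0 = 0$ and all-zero subbands mapping to all-zero descriptors.
* **Forward selection wraps one fast scorer.** The greedy search is scored
  by mean F1-macro over stratified 5-fold CV of a lightweight logistic
  classifier, for every downstream classifier family. Wrapping each family
  itself (an option still available via `forward_select(estimator = ...)`)
  multiplies the ~6000 candidate fits per dataset by the cost of SVM/forest
  training; the shared linear scorer keeps the selected subsets identical
  across families, which also makes the selector-vs-classifier comparison
  cleaner. Ties (duplicate columns) break toward the lower column index;
  equal CV scores across sizes break toward the smaller subset.
* **Boruta follows the reference defaults**: a shadow copy of every
  feature, re-permuted each iteration; impurity importance from a random
  forest whose tree count scales with the (real + shadow) feature count
  (floor 100); a hit when a real feature beats the *maximum* shadow
  importance; binomial tail tests under the two-step correction
  (Benjamini–Hochberg across undecided features *and* $p \le
  \alpha/\mathrm{iteration}$ for the repeated testing); leftover tentative
  features resolved by the median-importance rough fix (they enter the
  selection but keep the `tentative` decision).
* **Grid-search scoring is accuracy** (the conventional default of the
  procedure), while selection is scored by F1-macro — deliberately
  different. The random-forest tree-count axis (200/500/1000) is scored
  from one 1000-tree forest per depth/sampling/fold using per-tree
  predictions: trees are i.i.d. given the data, so the first $T$ trees are
  exactly a $T$-tree forest. The decision-tree criteria "entropy" and
  "log-loss" both map to rpart's information criterion and share one fit.
  Logistic regression is fitted as a ridge-penalized maximum-likelihood
  problem (C = 1, tolerance 1e-10) — the contract is the optimum, not a
  specific optimizer.
* **SVM ROC scores are signed margins**, not calibrated probabilities;
  random-forest scores are out-of-bag-free probability-forest votes; the
  ROC sweeps unique score thresholds with ties crossing simultaneously, and
  AUC is the trapezoidal area (equal to the Mann–Whitney statistic).
* **Derived seeds.** Each model's randomness comes from a deterministic
  integer hash of (master seed, dataset, selector, algorithm), so runs are
  bitwise reproducible and models are independent of execution order.

## What the synthetic generator does and does not emulate

`synth_normal()`, `synth_murmur()` and `synth_extrasystole()` produce
recordings with the structure the pipeline assumes: damped-sinusoid S1
(60–100 Hz) and S2 (80–150 Hz) bursts on a jittered 0.8-s cycle, murmurs as
band-limited 125–500 Hz noise filling the systolic S1→S2 interval (default
+6 dB relative to the S1 RMS), extrasystoles as 50–70%-length premature
cycles with a compensatory pause, low-level white background noise, and
durations both under and over 3 s (`make_corpus()` makes ~10% of abnormal
recordings short to exercise the extension path). All draws are shared
across classes for a given seed, so a murmur recording with the murmur gain
silenced *is* its paired normal template.

The generator deliberately encodes separable classes — the murmur band
lands in wavelet subbands D3/D4 and the rhythm disruption inflates
frame-statistic variability — so a correct pipeline must clearly beat
chance on it, and a pipeline with a leakage or orientation bug will not.
It is *not* a cardiac simulator: it has no respiratory or ambient noise
profile, no sensor coloration, no split S2, no gallops or clicks, no
subject-level variation in murmur morphology. Passing results on the
synthetic corpus therefore validate the *mechanics* of the pipeline, not
clinical performance; accuracies on it are far higher than anything
achievable on real auscultation data.

## Problem sizes used by the tests and the acceptance script

The shipped experiments run the full design at the package's reference
scale: a
synthetic corpus of 112 normal / 56 murmur / 56 extrasystole recordings,
binarized and balanced to 224, a 45-recording held-out test (23 normal /
22 abnormal), and all 120 models. Property-based checks use small signals
(16-sample frames for the DFT oracle, 32/64-sample signals for the wavelet
matrix oracle, 200×10 tables for the selection nulls) where the oracle is
exact.

## Known limitations

* Boruta-style selection inherits the finite-sample behavior of
  all-relevant selection: on small tables (hundreds of rows) a pure-noise
  feature whose chance correlation with the labels reaches ~0.15–0.2 is
  *consistently* more important than its shadows and will be confirmed —
  the binomial machinery cannot distinguish a stable finite-sample
  association from a true one. The package's tests document this null
  behavior honestly rather than tuning it away.
* The forward search is greedy and shares one wrapped scorer; it will not
  recover feature interactions that only a specific nonlinear family can
  exploit.
* The split is at recording level; no subject identifiers exist in the
  manifest schema, so subject-level leakage across recordings of the same
  patient cannot be excluded for real corpora that have such structure.
* WAV support covers RIFF PCM (8/16/24/32-bit) and IEEE float, mono-ized
  by averaging; exotic or proprietary stethoscope formats are out of scope,
  and no denoising or augmentation is applied anywhere.
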