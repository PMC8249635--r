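---
title: "Time-frequency and time-space sequence features for texture classification"
author: "frplstm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency and time-space sequence features for texture classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frplstm)
```

## Overview

`frplstm` classifies grayscale texture images by treating each image as a
one-dimensional signal and summarizing that signal with a short sequence of
four interpretable features, which a bidirectional LSTM then classifies.
The pipeline is:

1. **Vectorization.** A grayscale image $I \in \mathbb{R}^{M \times N}$ is
   unrolled column by column into a series
   $x = (I_{1,1}, \dots, I_{M,1}, I_{1,2}, \dots, I_{M,N})$ of length $MN$,
   carrying a nominal sampling rate $f_s$. Column stacking means vertical
   spatial structure with period $p$ rows becomes temporal oscillation at
   $f_s / p$ Hz.
2. **Time-frequency features.** A short-time Fourier transform (Hamming
   window, one-sided power spectrum) yields, per frame, the
   *instantaneous frequency* (power-weighted mean frequency, in Hz) and the
   *spectral entropy* (Shannon entropy of the normalized spectrum, scaled to
   $[0, 1]$ by $\log_2 F$ where $F$ is the number of frequency bins).
3. **Time-space features.** The series is cut into $T$ contiguous
   near-equal segments, one per spectrogram frame. Each segment is embedded
   in a delay-coordinate phase space, partitioned by fuzzy $c$-means, and a
   *fuzzy recurrence plot* (FRP) $R$ is formed by max–min composition of the
   membership matrix with itself: $R_{ij} = \max_q \min(u_{iq}, u_{jq})$,
   with $R_{ii} = 1$. Two entropies summarize $R$: the histogram entropy of
   its $L$-level quantization (*fuzzy recurrence image entropy*, FRIE) and
   the summed binary fuzzy-set entropy
   $\sum_{ij} -\mu \log_2 \mu - (1-\mu)\log_2(1-\mu)$
   (*fuzzy recurrence entropy*, FRE).
4. **Classification.** The resulting $T \times 4$ feature sequence
   (`if_hz`, `se`, `frie`, `fre`) is standardized per channel and fed to a
   bidirectional LSTM whose last valid hidden states from both directions
   are concatenated and mapped through a dense softmax layer.
5. **Class modeling.** Rather than training on the raw imbalanced pool, a
   target class keeps all of its samples while each other class is
   represented by a single donor sample replicated to match; the network
   therefore models the target class against caricatures of the
   alternatives.
6. **Evaluation.** Repeated stratified $k$-fold cross-validation reports
   accuracy, sensitivity, specificity, precision and F1 as mean ± standard
   deviation over the per-run fold means.

## Assumptions

* Input images are single-channel intensity rasters (color input is
  converted with BT.601 luma weights). Intensities may be on any affine
  scale; the standardizer absorbs offsets and gains at the classifier, and
  the spectrogram's per-frame mean removal absorbs them at feature
  extraction.
* Texture classes differ in their spatial statistics — dominant spatial
  frequency, spectral flatness, or recurrence structure — not merely in
  global brightness (per-frame detrending deliberately discards the mean).
* All images in a dataset share one size (or are resized with
  `resize_image()`), so all feature sequences share one length $T$; the
  classifier requires this only per training batch but class modeling and
  cross-validation assume it.

## Tunable parameters

| Parameter | Default | Role |
|---|---|---|
| `fs` | 300 Hz | Nominal sampling rate of the vectorized series. Purely a choice of units: it scales `if_hz` but cancels out of every standardized feature, so it never changes a classification. |
| `window_len`, `hop_len` | 128, 64 | STFT frame length and stride, in samples. 128 samples at 50% overlap gives $F = 65$ frequency bins and, for a 64×64 image (4096 samples), $T = 63$ frames — long enough for the LSTM, fine enough in frequency to separate the synthetic classes. Larger windows sharpen frequency resolution (and push white-noise scaled entropy closer to 1) at the cost of fewer frames. |
| `m`, `tau` | 1, 1 | Embedding dimension and delay for phase-space reconstruction. The defaults treat each sample as its own state, which is adequate for the short segments used here; raise `m` for signals whose dynamics need unfolding. |
| `c` | 3 | Number of fuzzy clusters. Small values keep the FRP coarse and the entropies stable on short segments; each segment must contain at least `c` distinct values or it falls back to the degenerate full-recurrence plot (FRIE = FRE = 0). |
| `w` | 2 | Fuzzy c-means weighting exponent. The conventional value; larger `w` blurs memberships and raises FRE. |
| `L` | 256 | Quantization levels for FRIE, matching 8-bit image convention; FRIE is then bounded by $\log_2 256 = 8$ bits. |
| `hidden_size` | 100 | LSTM units per direction. |
| `learning_rate` | 0.01 | Adam step size. |
| `grad_clip` | 1 | Global L2-norm gradient clipping threshold. |
| `l2` | 1e-4 | Weight decay on weight matrices (not biases). |
| `epochs` | 80 (2 classes) / 180 (more) | Training length when no early stop triggers. |
| `batch_size` | 150 (`frp_lstm`) / 16 (`repeated_kfold_cv`) | Minibatch size. The fitting default suits datasets of hundreds of sequences; cross-validation defaults to 16 because a fold's class-modeling training set here is ~72 sequences, and a full-batch setting would give one parameter update per epoch. |
| `loss_tol` | 1e-3 | Early stop: training ends once the mean epoch loss drops below this. Set `loss_tol = 0` to force the full epoch budget. |
| `k`, `runs` | 10, 10 | Folds and repetitions of cross-validation. Run $r$ is seeded with `seed + r - 1`, so any prefix of runs is reproducible on its own. |

## What the synthetic generator emulates

`generate_dataset()` builds labeled grayscale textures from three families:
sinusoidal **gratings** (`0.5 + 0.4 sin(2π m / period + phase)` plus
Gaussian noise, varying along rows so the vectorized series carries a clean
`fs / period` tone), **checkerboards** (square-wave analogue), and
**Gaussian random fields** with power-law spectra (amplitude
$\propto |k|^{-\alpha/2}$), which mimic the unstructured, scale-free
component of natural textures. These stand in for tissue-texture classes
whose discriminative content is spatial-frequency structure: the "coarse"
versus "fine" grating pair in `default_two_class_specs()` plays the role of
two tissue types with different dominant periodicities. What the surrogate
does **not** emulate is the morphological content of real micrographs —
nuclei, glands, staining variation — so accuracy on it says the pipeline
and classifier work, not that any particular biological problem is solved.

## Numerical choices

* **Per-frame detrending** (`detrend = TRUE`): images have a large DC
  luminance component; without mean removal the power-weighted mean
  frequency is dragged toward 0 Hz and ceases to track the texture's
  dominant frequency. Detrending is the default and can be disabled.
* **Power floor:** spectra are floored at `eps * max(max(P), 1)` before
  normalization, so silent frames are well-defined: a zero signal yields
  IF = $f_s/4$ (flat-spectrum mean) and scaled SE = 1.
* **Quantile initialization of fuzzy c-means:** centroids start at the
  $(2q-1)/(2c)$ quantiles of the first embedding coordinate, making the
  algorithm fully deterministic without consuming random numbers — a
  requirement for exact reproducibility of `ts_sequence()` under a seed.
  Points coinciding with a centroid get crisp membership (the usual
  zero-distance convention).
* **Single max–min composition** is the default FRP; `iterate = TRUE`
  composes to the max–min transitive closure instead. The closure is
  idempotent but washes out fine structure, so the single composition is
  used throughout the pipeline.
* **Degenerate segments** (fewer than `c` distinct values) skip clustering
  and return the all-ones FRP, giving FRIE = FRE = 0 — the natural limit
  for a constant signal.
* **Standardization** uses pooled per-channel mean and *population*
  standard deviation over all training frames, floored at 1e-8; the fitted
  standardizer is stored in the model and applied at prediction.
* **Tie-breaking** in `predict()` resolves equal posteriors to the
  lowest-indexed class, deterministically.
* **Segment layout:** `ts_sequence()` makes the first `len %% T` segments
  one sample longer, so segments are contiguous, exhaustive and within one
  sample of equal length; segments must have at least 8 samples.

## Problem sizes

The package's own experiments (tests, the acceptance script, the examples
below) use 64×64 images, 40 per class, 10-fold cross-validation with 2
repetitions and 30-epoch training — sizes chosen so a full run completes in
about a minute on one core while still exercising every stage at realistic
sequence lengths ($T = 63$). All knobs scale up: nothing in the code limits
image size, class count, epochs or repetitions.

## Worked example

```{r example, eval = FALSE}
ds <- generate_dataset(default_two_class_specs(), n_per_class = 40,
                       size = 64, seed = 7)
feats <- dataset_features(ds)
cv <- repeated_kfold_cv(feats, attr(feats, "labels"),
                        k = 10, runs = 2, seed = 7,
                        epochs = 30, batch_size = 16)
print(cv)
#> 2 run(s) of 10-fold stratified cross-validation (2 classes, target 'coarse')
#>   ACC  98.75 ± 1.77 %
#>   SEN  100.00 ± 0.00 %
#>   SPE  97.50 ± 3.54 %
#>   PRE  98.00 ± 2.83 %
#>   F1   0.989 ± 0.016
```

## Known limitations

* Column stacking is orientation-sensitive: textures differing only by a
  90° rotation produce different series. If orientation is a nuisance,
  augment or symmetrize upstream.
* With `window_len = 128` ($F = 65$ bins), the scaled spectral entropy of
  white noise converges to ≈ 0.898, not 1: the expectation of the scaled
  entropy of an exponential-power flat spectrum is
  $(\log_2 F - (1-\gamma)/\ln 2)/\log_2 F$, which approaches 1 only as
  $F \to \infty$. Use a larger window when near-maximal entropy readings on
  flat spectra matter.
* The LSTM is implemented in base R. It is exact and deterministic but not
  fast; hundreds of training sequences and tens of epochs are comfortable,
  tens of thousands are not.
* Multiclass problems are handled by a single softmax network over the
  class-modeling set; a one-vs-rest ensemble of binary models (one target
  class each) is possible by calling `build_class_modeling_set()` per class
  but is not automated.
* Cross-validation reports the full sensitivity/specificity/precision/F1
  panel only for two-class problems; with more classes only accuracy is
  summarized.
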