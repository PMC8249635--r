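# frplstm

Texture-image classification by recasting images as one-dimensional
signals, extracting sequential **time-frequency** (spectral) and
**time-space** (fuzzy-recurrence) features, and classifying the resulting
short feature sequences with a bidirectional LSTM trained under a
class-modeling scheme.

The intended audience is researchers working on histopathological or other
texture-dominated image classification who want an interpretable,
fully-deterministic pipeline in plain R: every feature has physical units
and a closed-form definition, and every stage — from the short-time Fourier
transform to the LSTM's backpropagation — is implemented in base R with no
compiled or deep-learning dependencies.

## Method

A grayscale image $I \in \mathbb{R}^{M\times N}$ is unrolled column by
column into a series $x$ of length $MN$ with nominal sampling rate $f_s$
(default 300 Hz). Two feature families are computed on a common grid of
$T$ frames:

* **Time-frequency**, from a short-time Fourier transform (Hamming window
  of 128 samples, hop 64, per-frame mean removal):
  * instantaneous frequency
    $\mathrm{IF}_t = \sum_f f\,P_t(f) \big/ \sum_f P_t(f)$ (Hz), the
    power-weighted mean frequency of frame $t$;
  * spectral entropy
    $\mathrm{SE}_t = -\sum_f p_t(f)\log_2 p_t(f) \big/ \log_2 F \in [0,1]$,
    where $p_t$ is the normalized frame spectrum over $F$ bins.
* **Time-space**, from $T$ contiguous segments of $x$: each segment is
  embedded in delay coordinates, partitioned by fuzzy $c$-means
  ($c = 3$, $w = 2$), and turned into a fuzzy recurrence plot
  $R_{ij} = \max_q \min(u_{iq}, u_{jq})$ with unit diagonal. Its
  *fuzzy recurrence image entropy* (FRIE, histogram entropy of the 256-level
  quantization of $R$) and *fuzzy recurrence entropy*
  (FRE, $\sum_{ij} -\mu\log_2\mu - (1-\mu)\log_2(1-\mu)$) summarize the
  recurrence texture.

The $T \times 4$ sequence (`if_hz`, `se`, `frie`, `fre`) is standardized
per channel and classified by a bidirectional LSTM (100 units per
direction, Adam, gradient clipping at norm 1, weight decay $10^{-4}$).
Training uses **class modeling**: the target class contributes all its
samples; every other class is represented by one donor sequence replicated
to match. Performance is reported by repeated stratified $k$-fold
cross-validation as mean ± SD of accuracy (ACC), sensitivity (SEN),
specificity (SPE), precision (PRE) and F1 over the per-run fold means.

See the methods vignette (`vignettes/frplstm-methods.Rmd`) for assumptions,
parameter rationale and numerical conventions.

## Worked example

All numbers below are the actual output of the code shown.

```r
library(frplstm)

img <- generate_grating(64, period = 6, noise_sd = 0.05, seed = 1)
series <- vectorize(img)
print(series)
#> signal series: 4096 samples, fs = 300 Hz (from 64x64 image)

feats1 <- image_features(img, label = "fine")
round(head(feats1, 3), 4)
#>        if_hz     se   frie      fre
#> [1,] 52.5971 0.4804 4.4518 606.0933
#> [2,] 52.5958 0.4722 4.5777 630.4131
#> [3,] 52.8465 0.4691 4.9795 775.5101
```

A period-6 grating at $f_s = 300$ Hz should oscillate at
$300/6 = 50$ Hz; the extracted instantaneous frequency sits near that, with
moderate spectral entropy (a noisy tone) and nonzero recurrence entropies.

```r
ds     <- generate_dataset(default_two_class_specs(), n_per_class = 40,
                           size = 64, seed = 7)
feats  <- dataset_features(ds)
labels <- attr(feats, "labels")
table(labels)
#> labels
#> coarse   fine
#>     40     40

cm  <- build_class_modeling_set(feats, labels, target_class = "coarse")
fit <- frp_lstm(cm$features[1:60], cm$labels[1:60], epochs = 20, seed = 1,
                batch_size = 16)
print(fit)
#> Bidirectional LSTM sequence classifier (frp_lstm)
#>   classes:      coarse, fine
#>   hidden size: 100 per direction
#>   trained on 60 sequences, 2 epochs (8 iterations)
#>   final loss 0.0000, final minibatch accuracy 100.0%

predict(fit, feats[1:4])
#> [1] coarse coarse coarse coarse
#> Levels: coarse fine
```

(The fit stops after 2 epochs because the mean epoch loss fell below the
`loss_tol = 1e-3` early-stopping threshold.)

```r
cv <- repeated_kfold_cv(feats, labels, k = 10, runs = 2, seed = 7,
                        epochs = 30, batch_size = 16)
print(cv)
#> 2 run(s) of 10-fold stratified cross-validation (2 classes, target 'coarse')
#>   ACC  98.75 ± 1.77 %
#>   SEN  100.00 ± 0.00 %
#>   SPE  97.50 ± 3.54 %
#>   PRE  98.00 ± 2.83 %
#>   F1   0.989 ± 0.016
```

The whole experiment (80 images → 80 feature sequences → 20 fold models)
runs in about a minute on one core and is bit-for-bit reproducible under
its seed.

## License

MIT (see `LICENSE`).
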