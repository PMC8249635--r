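# Shared fixtures: all built in code at test time.

# Linearly separable toy feature sequences: class "b" is offset by +5 on
# channel 1 (the IF channel). Sized for fast LSTM fits.
make_toy_features <- function(n_per_class = 10, len = 30, offset = 5,
                              seed = 42) {
  withr::with_seed(seed, {
    feats <- lapply(seq_len(2 * n_per_class), function(i) {
      base <- matrix(stats::rnorm(len * 4), len, 4)
      if (i > n_per_class) base[, 1] <- base[, 1] + offset
      feature_sequence(base,
                       label = if (i > n_per_class) "b" else "a")
    })
    list(features = feats,
         labels = factor(rep(c("a", "b"), each = n_per_class)))
  })
}

# A random row-normalized membership matrix posing as a converged fuzzy
# partition (for composition/entropy oracles).
random_partition <- function(N, c = 3, seed = 1) {
  U <- withr::with_seed(seed, matrix(stats::runif(N * c), N, c))
  U <- U / rowSums(U)
  structure(list(centroids = matrix(0, c, 1), U = U, w = 2, c = c,
                 iterations = 1L, converged = TRUE),
            class = "fuzzy_partition")
}

# Independent brute-force oracles (straight loops, no vectorization).
oracle_maxmin <- function(U) {
  N <- nrow(U); cc <- ncol(U)
  R <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    best <- 0
    for (q in seq_len(cc)) best <- max(best, min(U[i, q], U[j, q]))
    R[i, j] <- best
  }
  R
}

oracle_frie <- function(R, L = 256) {
  lev <- round(as.numeric(R) * (L - 1))
  H <- 0
  for (l in 0:(L - 1)) {
    p <- sum(lev == l) / length(lev)
    if (p > 0) H <- H - p * log2(p)
  }
  H
}

oracle_fre <- function(R) {
  tot <- 0
  for (mu in as.numeric(R)) {
    a <- if (mu > 0) -mu * log2(mu) else 0
    b <- if (mu < 1) -(1 - mu) * log2(1 - mu) else 0
    tot <- tot + a + b
  }
  tot
}

# Per-frame IF/SE oracle looping explicitly over bins (with the same power
# floor convention as the implementation).
oracle_if_se <- function(spec) {
  P <- spec$P
  P <- pmax(P, .Machine$double.eps * max(max(P), 1))
  Tn <- nrow(P); Fn <- ncol(P)
  if_hz <- numeric(Tn); se <- numeric(Tn)
  for (t in seq_len(Tn)) {
    tot <- 0; wsum <- 0
    for (m in seq_len(Fn)) {
      tot <- tot + P[t, m]
      wsum <- wsum + spec$freqs[m] * P[t, m]
    }
    if_hz[t] <- wsum / tot
    H <- 0
    for (m in seq_len(Fn)) {
      p <- P[t, m] / tot
      if (p > 0) H <- H - p * log2(p)
    }
    se[t] <- H / log2(Fn)
  }
  list(if_hz = if_hz, se = se)
}

# Hand-made spectrogram object (for closed-form IF/SE cases).
fake_spectrogram <- function(P, fs = 300) {
  structure(list(P = P, times = seq_len(nrow(P)),
                 freqs = seq(0, fs / 2, length.out = ncol(P)),
                 fs = fs, window_len = NA, hop_len = NA),
            class = "spectrogram")
}
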