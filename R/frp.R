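#' Delay-coordinate phase-space embedding
#'
#' Builds the embedded state matrix `x_i = (s_i, s_{i+tau}, ...,
#' s_{i+(m-1)tau})`. With the defaults `m = 1`, `tau = 1` the states are the
#' samples themselves.
#'
#' @param series A [signal_series()] or numeric vector.
#' @param m Embedding dimension (>= 1, default 1).
#' @param tau Time delay in samples (>= 1, default 1).
#' @return An `N x m` numeric matrix, `N = length - (m - 1) * tau`.
#' @export
embed_phase_space <- function(series, m = 1L, tau = 1L) {
  s <- if (inherits(series, "signal_series")) series$values else
    as.numeric(series)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1L || tau < 1L) stop("m and tau must be >= 1", call. = FALSE)
  N <- length(s) - (m - 1L) * tau
  if (N < 1L) {
    stop("series too short for embedding: need length > (m-1)*tau",
         call. = FALSE)
  }
  X <- matrix(0, N, m)
  for (j in seq_len(m)) X[, j] <- s[seq_len(N) + (j - 1L) * tau]
  X
}

#' Fuzzy c-means clustering
#'
#' Alternating optimization of the fuzzy c-means objective
#' `sum_i sum_q u_iq^w ||x_i - v_q||^2` with membership update
#' `u_iq = 1 / sum_k (d_iq / d_ik)^(2/(w-1))`. Initial centroids are placed
#' deterministically at the per-coordinate quantiles `(2q - 1) / (2c)` of the
#' data, so the fit involves no randomness. A point coinciding with one or
#' more centroids receives memberships split equally among the zero-distance
#' centroids (1 when unique).
#'
#' @param X Numeric `N x m` matrix of points (rows), e.g. from
#'   [embed_phase_space()], or a numeric vector.
#' @param c Number of clusters (>= 2, default 3).
#' @param w Fuzzifier exponent (> 1, default 2).
#' @param tol Convergence threshold on the maximum absolute membership change
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 100).
#' @return A `fuzzy_partition`: list with `centroids` (`c x m`), `U`
#'   (`N x c` memberships, rows summing to 1), `w`, `c`, `iterations`,
#'   `converged`.
#' @export
fuzzy_c_means <- function(X, c = 3L, w = 2, tol = 1e-5, max_iter = 100L) {
  if (!is.matrix(X)) X <- matrix(as.numeric(X), ncol = 1L)
  c <- as.integer(c)
  if (c < 2L) stop("c must be >= 2", call. = FALSE)
  if (w <= 1) stop("fuzzifier w must be > 1", call. = FALSE)
  if (nrow(unique(X)) < c) {
    stop("degenerate data: fewer than ", c, " distinct points",
         call. = FALSE)
  }
  N <- nrow(X)
  V <- apply(X, 2L, stats::quantile, probs = (2 * seq_len(c) - 1) / (2 * c),
             names = FALSE)
  V <- matrix(V, nrow = c)
  U <- matrix(1 / c, N, c)
  expo <- 1 / (w - 1)
  sqdist <- function(X, V) {
    # N x c matrix of squared Euclidean distances
    outer(rowSums(X^2), rep(1, nrow(V))) +
      outer(rep(1, nrow(X)), rowSums(V^2)) - 2 * tcrossprod(X, V)
  }
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D2 <- pmax(sqdist(X, V), 0)
    zero <- D2 < .Machine$double.eps
    inv <- (1 / pmax(D2, .Machine$double.xmin))^expo
    Unew <- inv / rowSums(inv)
    hit <- rowSums(zero) > 0L
    if (any(hit)) {
      Unew[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
    Uw <- Unew^w
    V <- (t(Uw) %*% X) / colSums(Uw)
    delta <- max(abs(Unew - U))
    U <- Unew
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  structure(list(centroids = V, U = U, w = w, c = c, iterations = iter,
                 converged = converged),
            class = "fuzzy_partition")
}

#' Build a fuzzy recurrence plot from a fuzzy partition
#'
#' The fuzzy similarity between states `x_i` and `x_j` is obtained by a
#' max-min composition through the cluster centroids:
#' `R(i,j) = max_q min(u_iq, u_jq)` (fuzzy transitivity). The diagonal is then
#' set to 1 (reflexivity); symmetry holds by construction. By default a single
#' composition is applied, as the transitivity relation is written;
#' `iterate = TRUE` repeats the composition of `R` with itself to the
#' max-min transitive closure.
#'
#' @param part A `fuzzy_partition` from [fuzzy_c_means()].
#' @param iterate Iterate the max-min composition to its fixpoint? Default
#'   `FALSE` (single composition).
#' @return An `N x N` matrix of class `frp` with entries in `[0, 1]`, unit
#'   diagonal and exact symmetry.
#' @export
build_frp <- function(part, iterate = FALSE) {
  stopifnot(inherits(part, "fuzzy_partition"))
  U <- part$U
  N <- nrow(U)
  R <- matrix(0, N, N)
  for (q in seq_len(part$c)) {
    R <- pmax(R, outer(U[, q], U[, q], pmin))
  }
  if (iterate) {
    repeat {
      R2 <- maxmin_compose(R, R)
      if (max(abs(R2 - R)) < 1e-12) break
      R <- R2
    }
  }
  diag(R) <- 1
  structure(R, class = c("frp", "matrix"))
}

# max-min composition of two square fuzzy relations (used for the optional
# transitive-closure iteration)
maxmin_compose <- function(A, B) {
  N <- nrow(A)
  out <- matrix(0, N, N)
  for (k in seq_len(N)) {
    out <- pmax(out, outer(A[, k], B[k, ], pmin))
  }
  out
}

#' Fuzzy recurrence image entropy (FRIE)
#'
#' Treats the fuzzy recurrence plot as a grayscale image with `L` gray
#' levels (`l = round(mu * (L - 1))`) and returns the Shannon entropy of the
#' gray-level histogram: `-sum_l p_l log2 p_l`, `p_l` the fraction of the
#' `N^2` entries at level `l`.
#'
#' @param R An `frp` matrix (or any numeric matrix with entries in `[0, 1]`).
#' @param L Number of gray levels (>= 2, default 256).
#' @return Entropy in bits, in `[0, log2(L)]`.
#' @export
frie <- function(R, L = 256L) {
  L <- as.integer(L)
  if (L < 2L) stop("L must be >= 2", call. = FALSE)
  lev <- round(unclass(R) * (L - 1))
  p <- tabulate(as.integer(lev) + 1L, nbins = L) / length(R)
  -sum(p[p > 0] * log2(p[p > 0]))
}

#' Fuzzy recurrence entropy (FRE)
#'
#' Sum over all entries of the fuzzy-set (binary) entropy of each membership:
#' `FRE = sum_ij [-mu log2 mu - (1 - mu) log2(1 - mu)]`, with
#' `0 log2 0 = 0`. Crisp plots (all entries 0 or 1) score 0.
#'
#' @param R An `frp` matrix (entries in `[0, 1]`).
#' @return Entropy in bits, in `[0, N^2]`.
#' @export
fre <- function(R) {
  mu <- as.numeric(R)
  h <- function(p) ifelse(p > 0, -p * log2(p), 0)
  sum(h(mu) + h(1 - mu))
}

#' Export a fuzzy recurrence plot as an 8-bit grayscale PNG
#'
#' @param R An `frp` matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_frp_png <- function(R, path) {
  png::writePNG(round(unclass(R) * 255) / 255, path)
  invisible(path)
}

#' Time-space feature sequence (FRIE and FRE)
#'
#' Splits the series into `n_segments` contiguous, near-equal segments (the
#' first `len %% n_segments` segments are one sample longer) and, per segment,
#' embeds the samples (defaults `m = 1`, `tau = 1`), clusters them with fuzzy
#' c-means (`c = 3`), builds the fuzzy recurrence plot and computes FRIE and
#' FRE. `n_segments` is chosen as the length of the time-frequency sequence so
#' the four feature channels align. Segments with fewer distinct values than
#' `c` clusters fall back to an all-ones plot (every state fully recurrent),
#' giving FRIE = FRE = 0.
#'
#' @param series A [signal_series()] or numeric vector.
#' @param n_segments Number of segments `T` (the TF sequence length).
#' @param m,tau Embedding dimension and delay (defaults 1, 1).
#' @param c Number of fuzzy clusters (default 3).
#' @param L Gray levels for FRIE (default 256).
#' @param w,tol,max_iter Fuzzy c-means settings (see [fuzzy_c_means()]).
#' @param min_segment Minimum usable segment length in samples (default 8).
#' @return A `ts_sequence` object: list with `frie`, `fre` (length
#'   `n_segments`, bits) and `segment_bounds` (2-column matrix of 1-based
#'   inclusive start/end indices).
#' @export
ts_sequence <- function(series, n_segments, m = 1L, tau = 1L, c = 3L,
                        L = 256L, w = 2, tol = 1e-5, max_iter = 100L,
                        min_segment = 8L) {
  s <- if (inherits(series, "signal_series")) series$values else
    as.numeric(series)
  n_segments <- as.integer(n_segments)
  len <- length(s)
  if (n_segments < 1L) stop("n_segments must be >= 1", call. = FALSE)
  base <- len %/% n_segments
  if (base < min_segment) {
    stop("series of length ", len, " cannot be split into ", n_segments,
         " segments of at least ", min_segment, " samples", call. = FALSE)
  }
  sizes <- rep(base, n_segments)
  extra <- len %% n_segments
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  frie_v <- numeric(n_segments)
  fre_v <- numeric(n_segments)
  for (k in seq_len(n_segments)) {
    seg <- s[starts[k]:ends[k]]
    X <- embed_phase_space(seg, m = m, tau = tau)
    if (nrow(unique(X)) < c) {
      # degenerate segment: all states mutually identical -> full recurrence
      next  # all-ones FRP has FRIE = 0 and FRE = 0
    }
    part <- fuzzy_c_means(X, c = c, w = w, tol = tol, max_iter = max_iter)
    R <- build_frp(part)
    frie_v[k] <- frie(R, L = L)
    fre_v[k] <- fre(R)
  }
  structure(list(frie = frie_v, fre = fre_v,
                 segment_bounds = cbind(start = starts, end = ends)),
            class = "ts_sequence")
}

#' @export
print.ts_sequence <- function(x, ...) {
  cat("time-space sequence: ", length(x$frie), " segments\n  FRIE [bits]: ",
      sep = "")
  cat(sprintf("%.3f", stats::quantile(x$frie, c(0, .5, 1))), sep = " / ")
  cat("  (min/median/max)\n  FRE  [bits]: ")
  cat(sprintf("%.1f", stats::quantile(x$fre, c(0, .5, 1))), sep = " / ")
  cat("\n")
  invisible(x)
}

#' Write a time-space sequence to CSV
#'
#' Columns: `segment`, `start`, `end`, `frie_bits`, `fre_bits`.
#'
#' @param ts A `ts_sequence`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ts_csv <- function(ts, path) {
  utils::write.csv(data.frame(segment = seq_along(ts$frie),
                              start = ts$segment_bounds[, "start"],
                              end = ts$segment_bounds[, "end"],
                              frie_bits = ts$frie, fre_bits = ts$fre),
                   path, row.names = FALSE)
  invisible(path)
}
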