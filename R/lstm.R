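# Bidirectional LSTM internals: parameter initialization, forward pass,
# backpropagation through time, Adam updates. Everything operates on plain
# matrices; a parameter set is a named list
#   Wx_f (D x 4H), Wh_f (H x 4H), b_f (4H),   forward direction
#   Wx_b, Wh_b, b_b,                          backward direction
#   Wd (2H x K), bd (K)                       dense output layer
# with gate blocks ordered [input | forget | cell | output] along the 4H
# axis. The classifier reads the last valid time step of each direction
# (forward at t = len, backward at its own last step, i.e. t = 1 of the
# original sequence), concatenates them and applies dense + softmax.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_bilstm <- function(D, H, K) {
  b0 <- numeric(4L * H)
  b0[(H + 1L):(2L * H)] <- 1   # unit forget-gate bias
  list(
    Wx_f = glorot(D, 4L * H), Wh_f = glorot(H, 4L * H), b_f = b0,
    Wx_b = glorot(D, 4L * H), Wh_b = glorot(H, 4L * H), b_b = b0,
    Wd = glorot(2L * H, K), bd = numeric(K)
  )
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  out <- skeleton
  pos <- 0L
  for (nm in names(skeleton)) {
    n <- length(skeleton[[nm]])
    v <- vec[(pos + 1L):(pos + n)]
    dim(v) <- dim(skeleton[[nm]])
    out[[nm]] <- v
    pos <- pos + n
  }
  out
}

# stack a list of standardized T x D feature matrices into a zero-padded
# [B, D, Tmax] array plus the per-sequence lengths
stack_sequences <- function(seqs) {
  B <- length(seqs)
  D <- ncol(seqs[[1L]])
  lens <- vapply(seqs, nrow, integer(1L))
  Tmax <- max(lens)
  X <- array(0, c(B, D, Tmax))
  for (b in seq_len(B)) X[b, , seq_len(lens[b])] <- t(unclass(seqs[[b]]))
  list(X = X, lens = lens)
}

reverse_sequences <- function(X, lens) {
  out <- X * 0
  for (b in seq_len(dim(X)[1L])) {
    out[b, , seq_len(lens[b])] <- X[b, , lens[b]:1L]
  }
  out
}

lstm_dir_forward <- function(X, lens, Wx, Wh, b) {
  B <- dim(X)[1L]; D <- dim(X)[2L]; Tmax <- dim(X)[3L]
  H <- nrow(Wh)
  gi <- seq_len(H); gf <- H + gi; gg <- 2L * H + gi; go <- 3L * H + gi
  Ia <- vector("list", Tmax); Fa <- Ia; Ga <- Ia; Oa <- Ia
  Ca <- Ia; TCa <- Ia; Ha <- Ia
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  brow <- rep(b, each = B)
  for (t in seq_len(Tmax)) {
    xt <- matrix(X[, , t], B, D)
    z <- xt %*% Wx + h %*% Wh + brow
    i <- sigmoid(z[, gi, drop = FALSE])
    f <- sigmoid(z[, gf, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE])
    o <- sigmoid(z[, go, drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    Ia[[t]] <- i; Fa[[t]] <- f; Ga[[t]] <- g; Oa[[t]] <- o
    Ca[[t]] <- cc; TCa[[t]] <- tc; Ha[[t]] <- h
  }
  hlast <- matrix(0, B, H)
  for (b2 in seq_len(B)) hlast[b2, ] <- Ha[[lens[b2]]][b2, ]
  list(hlast = hlast, Ia = Ia, Fa = Fa, Ga = Ga, Oa = Oa, Ca = Ca,
       TCa = TCa, Ha = Ha)
}

lstm_dir_backward <- function(X, lens, Wx, Wh, cache, dHlast) {
  B <- dim(X)[1L]; D <- dim(X)[2L]; Tmax <- dim(X)[3L]
  H <- nrow(Wh)
  dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(4L * H)
  dh <- matrix(0, B, H); dc <- matrix(0, B, H)
  zero <- matrix(0, B, H)
  tWh <- t(Wh)
  for (t in Tmax:1L) {
    at_end <- lens == t
    if (any(at_end)) dh[at_end, ] <- dh[at_end, ] + dHlast[at_end, ]
    i <- cache$Ia[[t]]; f <- cache$Fa[[t]]; g <- cache$Ga[[t]]
    o <- cache$Oa[[t]]; tc <- cache$TCa[[t]]
    cprev <- if (t > 1L) cache$Ca[[t - 1L]] else zero
    hprev <- if (t > 1L) cache$Ha[[t - 1L]] else zero
    do <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    di <- dc * g
    dg <- dc * i
    df <- dc * cprev
    dZ <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g^2), do * o * (1 - o))
    xt <- matrix(X[, , t], B, D)
    dWx <- dWx + crossprod(xt, dZ)
    dWh <- dWh + crossprod(hprev, dZ)
    db <- db + colSums(dZ)
    dh <- dZ %*% tWh
    dc <- dc * f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

bilstm_forward <- function(params, X, lens) {
  fwd <- lstm_dir_forward(X, lens, params$Wx_f, params$Wh_f, params$b_f)
  Xr <- reverse_sequences(X, lens)
  bwd <- lstm_dir_forward(Xr, lens, params$Wx_b, params$Wh_b, params$b_b)
  Hcat <- cbind(fwd$hlast, bwd$hlast)
  logits <- Hcat %*% params$Wd + rep(params$bd, each = nrow(Hcat))
  logits <- logits - apply(logits, 1L, max)
  e <- exp(logits)
  probs <- e / rowSums(e)
  list(fwd = fwd, bwd = bwd, Xr = Xr, Hcat = Hcat, probs = probs)
}

# cross-entropy gradient -> dense layer -> both directions; returns the full
# gradient in the parameter layout (L2 on weight matrices, not biases)
bilstm_backward <- function(params, X, lens, fw, y_onehot, l2 = 0) {
  B <- nrow(y_onehot)
  dlogits <- (fw$probs - y_onehot) / B
  dWd <- crossprod(fw$Hcat, dlogits)
  dbd <- colSums(dlogits)
  dHcat <- dlogits %*% t(params$Wd)
  H <- nrow(params$Wh_f)
  gf <- lstm_dir_backward(X, lens, params$Wx_f, params$Wh_f, fw$fwd,
                          dHcat[, seq_len(H), drop = FALSE])
  gb <- lstm_dir_backward(fw$Xr, lens, params$Wx_b, params$Wh_b, fw$bwd,
                          dHcat[, H + seq_len(H), drop = FALSE])
  g <- list(Wx_f = gf$Wx, Wh_f = gf$Wh, b_f = gf$b,
            Wx_b = gb$Wx, Wh_b = gb$Wh, b_b = gb$b,
            Wd = dWd, bd = dbd)
  if (l2 > 0) {
    for (nm in c("Wx_f", "Wh_f", "Wx_b", "Wh_b", "Wd")) {
      g[[nm]] <- g[[nm]] + l2 * params[[nm]]
    }
  }
  g
}

clip_gradient <- function(gvec, threshold) {
  nrm <- sqrt(sum(gvec^2))
  if (is.finite(nrm) && nrm > threshold) gvec * (threshold / nrm) else gvec
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, theta = theta - lr * mhat / (sqrt(vhat) + eps))
}
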