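# Minimal neural-network engine used by the architecture families: 1-D
# convolution over one-hot DNA (via an im2col expansion), non-overlapping
# max pooling, ReLU, dense layers, a bidirectional LSTM with hand-written
# backpropagation through time, and Adam. Everything operates on batch
# matrices; analytic gradients are verified against finite differences in
# the test suite.
#
# Batch encoding: a batch of B equal-length sequences is a B x 4L matrix
# whose row b is the 4 x L one-hot matrix of sequence b flattened
# column-major, i.e. column (l-1)*4 + c holds base channel c at position l.

# encode a character vector of equal-length sequences as a B x 4L matrix
encode_batch <- function(seqs) {
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L)) {
    stop("sequences in a batch must have equal length (offender at index ",
         which(nchar(seqs) != L)[1L], ")")
  }
  B <- length(seqs)
  all_ch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  hit <- match(all_ch, BASES)
  ok <- which(!is.na(hit))
  bad <- all_ch[is.na(hit)]
  if (length(bad) && any(!bad %in% "N")) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  X <- matrix(0, B, 4L * L)
  b_idx <- ((ok - 1L) %/% L) + 1L
  l_idx <- ((ok - 1L) %% L) + 1L
  X[b_idx + B * ((l_idx - 1L) * 4L + hit[ok] - 1L)] <- 1
  X
}

# ---- initialisation --------------------------------------------------------

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# ---- convolution (cross-correlation) ---------------------------------------

# W: (4k x F) filter bank, one column per filter; returns the response at
# every window position as a (B*P) x F matrix with row index b + (j-1)*B.
conv_forward <- function(X, W, b, L, k) {
  P <- L - k + 1L
  offs <- seq_len(4L * k)
  base <- (seq_len(P) - 1L) * 4L
  colmap <- as.vector(outer(offs, base, "+"))
  A <- X[, colmap, drop = FALSE]
  a <- array(A, c(nrow(X), 4L * k, P))
  m <- matrix(aperm(a, c(1L, 3L, 2L)), nrow(X) * P, 4L * k)
  Z <- m %*% W
  Z <- Z + matrix(b, nrow(Z), length(b), byrow = TRUE)
  list(Z = Z, m = m, P = P)
}

conv_backward <- function(cache, dZ) {
  list(W = crossprod(cache$m, dZ), b = colSums(dZ))
}

# ---- max pooling over positions + ReLU -------------------------------------

# Z: (B*P) x F conv output. Non-overlapping pooling of width p over the P
# positions (trailing remainder dropped), then ReLU. Returns activations as
# a (B, T, F) array plus the argmax/negativity masks for the backward pass.
pool_relu_forward <- function(Z, B, F_, p) {
  P <- nrow(Z) / B
  T_ <- P %/% p
  if (T_ < 1L) stop("pooling width ", p, " exceeds the ", P, " conv positions")
  arr <- array(Z, c(B, P, F_))
  pooled <- arr[, seq(1L, by = p, length.out = T_), , drop = FALSE]
  amax <- array(1L, c(B, T_, F_))
  if (p > 1L) {
    for (i in 2:p) {
      sl <- arr[, seq(i, by = p, length.out = T_), , drop = FALSE]
      upd <- sl > pooled
      amax[upd] <- i
      pooled[upd] <- sl[upd]
    }
  }
  dim(pooled) <- c(B, T_, F_)
  neg <- pooled < 0
  act <- pooled
  act[neg] <- 0
  list(act = act, amax = amax, neg = neg, B = B, P = P, F_ = F_, T_ = T_,
       p = p)
}

pool_relu_backward <- function(cache, dact) {
  dact[cache$neg] <- 0
  B <- cache$B; T_ <- cache$T_; F_ <- cache$F_; P <- cache$P; p <- cache$p
  bb <- rep(seq_len(B), times = T_ * F_)
  tt <- rep(rep(seq_len(T_), each = B), times = F_)
  ff <- rep(seq_len(F_), each = B * T_)
  pos <- (tt - 1L) * p + as.vector(cache$amax)
  lin <- bb + B * (pos - 1L) + B * P * (ff - 1L)
  dZ <- numeric(B * P * F_)
  dZ[lin] <- as.vector(dact)
  matrix(dZ, B * P, F_)
}

# flatten a (B, T, F) activation array to B x (T*F)
flat3 <- function(act) {
  d <- dim(act)
  dim(act) <- c(d[1L], d[2L] * d[3L])
  act
}

# ---- dense -----------------------------------------------------------------

dense_forward <- function(X, W, b) {
  X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE)
}

dense_backward <- function(X, W, dZ) {
  list(W = crossprod(X, dZ), b = colSums(dZ), dX = tcrossprod(dZ, W))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- LSTM ------------------------------------------------------------------

# one direction; xs is a list of T matrices (B x Fin); gate order i, f, g, o.
# Returns the per-step hidden states: the CNN-BiLSTM feeds the full output
# sequence (not just the final state) to the dense stage, so positional
# signal survives the recurrence.
lstm_forward <- function(xs, Wx, Wh, b) {
  B <- nrow(xs[[1L]])
  H <- nrow(Wh)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  hs <- vector("list", length(xs))
  caches <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    A <- xs[[t]] %*% Wx + h %*% Wh + matrix(b, B, 4L * H, byrow = TRUE)
    ig <- sigmoid(A[, 1:H, drop = FALSE])
    fg <- sigmoid(A[, H + 1:H, drop = FALSE])
    gg <- tanh(A[, 2L * H + 1:H, drop = FALSE])
    og <- sigmoid(A[, 3L * H + 1:H, drop = FALSE])
    c_new <- fg * cc + ig * gg
    tc <- tanh(c_new)
    h_new <- og * tc
    caches[[t]] <- list(x = xs[[t]], hprev = h, cprev = cc, i = ig, f = fg,
                        g = gg, o = og, c = c_new, tc = tc)
    h <- h_new; cc <- c_new
    hs[[t]] <- h_new
  }
  list(h = h, hs = hs, caches = caches)
}

# backprop through time; dh_list carries the gradient on each step's hidden
# state (from the flattened output-sequence feature).
lstm_backward <- function(caches, Wx, Wh, dh_list) {
  H <- nrow(Wh)
  B <- nrow(caches[[1L]]$x)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4L * H)
  dh <- matrix(0, B, H)
  dc <- matrix(0, B, H)
  dxs <- vector("list", length(caches))
  for (t in rev(seq_along(caches))) {
    cc <- caches[[t]]
    dh <- dh + dh_list[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$cprev
    dc <- dc * cc$f
    dA <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, dA)
    dWh <- dWh + crossprod(cc$hprev, dA)
    db <- db + colSums(dA)
    dxs[[t]] <- tcrossprod(dA, Wx)
    dh <- tcrossprod(dA, Wh)
  }
  list(Wx = dWx, Wh = dWh, b = db, dxs = dxs)
}

# bidirectional wrapper: independent parameter sets per direction. The
# feature is the full output sequence, position-aligned: for each step t the
# forward state at t and the backward state at t (from the reversed pass)
# are concatenated, giving a B x (T * 2H) matrix.
bilstm_forward <- function(xs, par) {
  T_ <- length(xs)
  fwd <- lstm_forward(xs, par$fwd$Wx, par$fwd$Wh, par$fwd$b)
  bwd <- lstm_forward(rev(xs), par$bwd$Wx, par$bwd$Wh, par$bwd$b)
  feat <- do.call(cbind, lapply(seq_len(T_), function(t) {
    cbind(fwd$hs[[t]], bwd$hs[[T_ - t + 1L]])
  }))
  list(feat = feat, fwd = fwd, bwd = bwd)
}

bilstm_backward <- function(cache, par, dfeat) {
  H <- ncol(cache$fwd$h)
  T_ <- length(cache$fwd$caches)
  dh_fwd <- vector("list", T_)
  dh_bwd <- vector("list", T_)
  for (t in seq_len(T_)) {
    block <- (t - 1L) * 2L * H
    dh_fwd[[t]] <- dfeat[, block + 1:H, drop = FALSE]
    dh_bwd[[T_ - t + 1L]] <- dfeat[, block + H + 1:H, drop = FALSE]
  }
  gf <- lstm_backward(cache$fwd$caches, par$fwd$Wx, par$fwd$Wh, dh_fwd)
  gb <- lstm_backward(cache$bwd$caches, par$bwd$Wx, par$bwd$Wh, dh_bwd)
  dxs <- Map(`+`, gf$dxs, rev(gb$dxs))
  list(grads = list(fwd = gf[c("Wx", "Wh", "b")], bwd = gb[c("Wx", "Wh", "b")]),
       dxs = dxs)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) return(lapply(p, walk))
    list(m = array(0, dim = dim(p) %||% length(p)), v = array(0, dim = dim(p) %||% length(p)))
  }
  list(state = lapply(params, walk), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# params and grads share structure; grads may contain NULL (frozen branches)
adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  t_ <- opt$t
  walk <- function(p, g, s) {
    if (is.null(g)) return(list(p = p, s = s))
    if (is.list(p)) {
      keys <- if (!is.null(names(p)) && all(nzchar(names(p)))) {
        names(p)
      } else {
        seq_along(p)
      }
      for (i in keys) {
        res <- walk(p[[i]], g[[i]], s[[i]])
        p[[i]] <- res$p; s[[i]] <- res$s
      }
      return(list(p = p, s = s))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mhat <- s$m / (1 - beta1^t_)
    vhat <- s$v / (1 - beta2^t_)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    list(p = p, s = s)
  }
  res <- walk(params, grads, opt$state)
  list(params = res$p, opt = list(state = res$s, t = t_))
}
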