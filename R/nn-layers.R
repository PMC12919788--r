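# Differentiable layer primitives with hand-written backward passes.
#
# Layout contract: per-position activations are (B*L) x d matrices,
# record-major (row (b-1)*L + i = position i of record b). Every forward
# returns what its backward needs; backwards return input gradients plus
# parameter gradients in the same shapes as the parameters.

LN_EPS <- 1e-5

add_bias <- function(M, b) M + rep(b, each = nrow(M))

linear_fwd <- function(X, W, b) add_bias(X %*% W, b)

linear_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# Shift rows by `o` positions within each length-L record, zero-filling
# rows that fall outside the record (zero padding for the convolution).
shift_rows <- function(H, L, B, o) {
  if (o == 0L) return(H)
  pos <- rep(seq_len(L), B)
  src <- pos + o
  valid <- src >= 1L & src <= L
  base <- rep(seq.int(0L, by = L, length.out = B), each = L)
  idx <- ifelse(valid, base + src + 1L, 1L)  # row 1 of Hp is the zero row
  Hp <- rbind(0, H)
  Hp[idx, , drop = FALSE]
}

# 1D convolution over positions, kernel k (odd), zero padding (k-1)/2 so the
# output keeps length L. W is a list of k matrices (c_in x c_out), one per
# kernel offset -(k-1)/2 .. +(k-1)/2.
conv1d_fwd <- function(H, W, b, L, B) {
  k <- length(W)
  half <- (k - 1L) %/% 2L
  Y <- matrix(0, nrow(H), length(b))
  for (j in seq_len(k)) {
    Y <- Y + shift_rows(H, L, B, j - 1L - half) %*% W[[j]]
  }
  add_bias(Y, b)
}

conv1d_bwd <- function(dY, H, W, L, B) {
  k <- length(W)
  half <- (k - 1L) %/% 2L
  dH <- matrix(0, nrow(H), nrow(W[[1]]))
  dW <- vector("list", k)
  for (j in seq_len(k)) {
    o <- j - 1L - half
    dH <- dH + shift_rows(dY, L, B, -o) %*% t(W[[j]])
    dW[[j]] <- crossprod(shift_rows(H, L, B, o), dY)
  }
  list(dH = dH, dW = dW, db = colSums(dY))
}

layernorm_fwd <- function(H, gamma, beta) {
  mu <- rowMeans(H)
  xc <- H - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(Y = add_bias(xhat * rep(gamma, each = nrow(H)), beta),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dxhat <- dY * rep(gamma, each = n)
  xhat <- cache$xhat
  dH <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dH = dH, dgamma = colSums(dY * xhat), dbeta = colSums(dY))
}

relu_fwd <- function(X) {
  Y <- X
  Y[Y < 0] <- 0
  Y
}

relu_bwd <- function(dY, X) dY * (X > 0)

# Inverted dropout; draws its mask from the current RNG stream so training
# runs are reproducible under set.seed. p = 0 or eval mode is the identity.
dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(Y = X * mask, mask = mask)
}

dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

attention_fwd <- function(H, par, L, B, n_heads) {
  Q <- linear_fwd(H, par$Wq, par$bq)
  K <- linear_fwd(H, par$Wk, par$bk)
  V <- linear_fwd(H, par$Wv, par$bv)
  at <- attn_forward_cpp(Q, K, V, L, n_heads)
  Y <- linear_fwd(at$O, par$Wo, par$bo)
  list(Y = Y, Q = Q, K = K, V = V, A = at$A, O = at$O)
}

attention_bwd <- function(dY, cache, H, par, L, n_heads) {
  lo <- linear_bwd(dY, cache$O, par$Wo)
  ab <- attn_backward_cpp(lo$dX, cache$Q, cache$K, cache$V, cache$A, L, n_heads)
  lq <- linear_bwd(ab$dQ, H, par$Wq)
  lk <- linear_bwd(ab$dK, H, par$Wk)
  lv <- linear_bwd(ab$dV, H, par$Wv)
  list(dH = lq$dX + lk$dX + lv$dX,
       grads = list(Wq = lq$dW, bq = lq$db, Wk = lk$dW, bk = lk$db,
                    Wv = lv$dW, bv = lv$db, Wo = lo$dW, bo = lo$db))
}

# One post-LN transformer encoder block:
#   Z1 = LN1(H + Dropout(Attn(H)));  Z2 = LN2(Z1 + Dropout(FFN(Z1)))
transformer_block_fwd <- function(H, par, L, B, n_heads, p_drop, training) {
  at <- attention_fwd(H, par, L, B, n_heads)
  do1 <- dropout_fwd(at$Y, p_drop, training)
  ln1 <- layernorm_fwd(H + do1$Y, par$g1, par$be1)
  U <- linear_fwd(ln1$Y, par$Wf1, par$bf1)
  Ur <- relu_fwd(U)
  FF <- linear_fwd(Ur, par$Wf2, par$bf2)
  do2 <- dropout_fwd(FF, p_drop, training)
  ln2 <- layernorm_fwd(ln1$Y + do2$Y, par$g2, par$be2)
  list(Y = ln2$Y,
       cache = list(H = H, at = at, do1 = do1, ln1 = ln1, U = U, Ur = Ur,
                    do2 = do2, ln2 = ln2))
}

transformer_block_bwd <- function(dY, cache, par, L, n_heads) {
  l2 <- layernorm_bwd(dY, cache$ln2, par$g2)
  dF <- dropout_bwd(l2$dH, cache$do2$mask)
  lf2 <- linear_bwd(dF, cache$Ur, par$Wf2)
  dU <- relu_bwd(lf2$dX, cache$U)
  lf1 <- linear_bwd(dU, cache$ln1$Y, par$Wf1)
  dZ1 <- l2$dH + lf1$dX
  l1 <- layernorm_bwd(dZ1, cache$ln1, par$g1)
  dAttnY <- dropout_bwd(l1$dH, cache$do1$mask)
  ab <- attention_bwd(dAttnY, cache$at, cache$H, par, L, n_heads)
  grads <- c(ab$grads,
             list(g1 = l1$dgamma, be1 = l1$dbeta,
                  Wf1 = lf1$dW, bf1 = lf1$db, Wf2 = lf2$dW, bf2 = lf2$db,
                  g2 = l2$dgamma, be2 = l2$dbeta))
  list(dH = l1$dH + ab$dH, grads = grads)
}
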