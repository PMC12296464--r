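## Transformer layer primitives with explicit forward/backward passes.
## All activations are (rows x features) matrices; a "sequence" of B tiles
## with T tokens each is stored as a (B*T) x D matrix grouped by tile.
## Gradients are validated against finite differences in the test suite.

LN_EPS <- 1e-6

addBias <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)

linearFwd <- function(X, W, b) {
  list(out = addBias(X %*% W, b), X = X)
}

linearBwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

layerNormFwd <- function(X, g, b) {
  m <- rowMeans(X)
  xc <- X - m
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  out <- addBias(xhat * matrix(g, nrow(X), length(g), byrow = TRUE), b)
  list(out = out, xhat = xhat, inv = inv)
}

layerNormBwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * matrix(g, nrow(dY), length(g), byrow = TRUE)
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  # per-row: dx = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

GELU_C <- sqrt(2 / pi)

geluFwd <- function(X) {
  inner <- GELU_C * (X + 0.044715 * X^3)
  th <- tanh(inner)
  list(out = 0.5 * X * (1 + th), th = th)
}

geluBwd <- function(dY, X, cache) {
  th <- cache$th
  dInner <- GELU_C * (1 + 3 * 0.044715 * X^2)
  dY * (0.5 * (1 + th) + 0.5 * X * (1 - th^2) * dInner)
}

softmaxRows <- function(S) {
  e <- exp(S - apply(S, 1L, max))
  e / rowSums(e)
}

## Multi-head self-attention over B independent sequences of length T.
attentionFwd <- function(X, p, B, T, H) {
  D <- ncol(X)
  dh <- D %/% H
  q <- linearFwd(X, p$Wq, p$bq)
  k <- linearFwd(X, p$Wk, p$bk)
  v <- linearFwd(X, p$Wv, p$bv)
  O <- matrix(0, nrow(X), D)
  A <- vector("list", B * H)
  scl <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Ab <- softmaxRows(tcrossprod(q$out[rows, cols, drop = FALSE],
                                   k$out[rows, cols, drop = FALSE]) * scl)
      A[[(b - 1L) * H + h]] <- Ab
      O[rows, cols] <- Ab %*% v$out[rows, cols, drop = FALSE]
    }
  }
  o <- linearFwd(O, p$Wo, p$bo)
  list(out = o$out, q = q, k = k, v = v, O = O, A = A,
       oCache = o, B = B, T = T, H = H, dh = dh, scl = scl)
}

attentionBwd <- function(dY, cache, p) {
  B <- cache$B; T <- cache$T; H <- cache$H; dh <- cache$dh
  ob <- linearBwd(dY, cache$oCache, p$Wo)
  dO <- ob$dX
  dQ <- matrix(0, nrow(dY), ncol(p$Wq))
  dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[(b - 1L) * H + h]]
      dOb <- dO[rows, cols, drop = FALSE]
      vb <- cache$v$out[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOb, vb)
      dV[rows, cols] <- crossprod(A, dOb)
      dS <- (dA - rowSums(dA * A)) * A * cache$scl
      dQ[rows, cols] <- dS %*% cache$k$out[rows, cols, drop = FALSE]
      dK[rows, cols] <- crossprod(dS, cache$q$out[rows, cols, drop = FALSE])
    }
  }
  gq <- linearBwd(dQ, cache$q, p$Wq)
  gk <- linearBwd(dK, cache$k, p$Wk)
  gv <- linearBwd(dV, cache$v, p$Wv)
  list(
    dX = gq$dX + gk$dX + gv$dX,
    grads = list(Wq = gq$dW, bq = gq$db, Wk = gk$dW, bk = gk$db,
                 Wv = gv$dW, bv = gv$db, Wo = ob$dW, bo = ob$db)
  )
}

## One pre-LN transformer block: x + MHA(LN1(x)), then x + MLP(LN2(x)).
blockFwd <- function(X, p, B, T, H) {
  ln1 <- layerNormFwd(X, p$ln1g, p$ln1b)
  att <- attentionFwd(ln1$out, p, B, T, H)
  X1 <- X + att$out
  ln2 <- layerNormFwd(X1, p$ln2g, p$ln2b)
  f1 <- linearFwd(ln2$out, p$W1, p$b1)
  g <- geluFwd(f1$out)
  f2 <- linearFwd(g$out, p$W2, p$b2)
  list(out = X1 + f2$out, ln1 = ln1, att = att, ln2 = ln2,
       f1 = f1, g = g, f2 = f2)
}

blockBwd <- function(dY, cache, p, B, T, H) {
  b2 <- linearBwd(dY, cache$f2, p$W2)
  dG <- geluBwd(b2$dX, cache$f1$out, cache$g)
  b1 <- linearBwd(dG, cache$f1, p$W1)
  l2 <- layerNormBwd(b1$dX, cache$ln2, p$ln2g)
  dX1 <- dY + l2$dX
  ab <- attentionBwd(dX1, cache$att, p)
  l1 <- layerNormBwd(ab$dX, cache$ln1, p$ln1g)
  grads <- c(
    list(ln1g = l1$dg, ln1b = l1$db, ln2g = l2$dg, ln2b = l2$db,
         W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db),
    ab$grads
  )
  list(dX = dX1 + l1$dX, grads = grads)
}

## Stack of blocks with final LayerNorm (used by encoder and decoder).
stackFwd <- function(X, blocks, lnG, lnB, B, T, H) {
  caches <- vector("list", length(blocks))
  for (l in seq_along(blocks)) {
    c_ <- blockFwd(X, blocks[[l]], B, T, H)
    caches[[l]] <- c_
    X <- c_$out
  }
  fin <- layerNormFwd(X, lnG, lnB)
  list(out = fin$out, caches = caches, fin = fin)
}

stackBwd <- function(dY, cache, blocks, lnG, B, T, H) {
  fin <- layerNormBwd(dY, cache$fin, lnG)
  dX <- fin$dX
  grads <- vector("list", length(blocks))
  for (l in rev(seq_along(blocks))) {
    bb <- blockBwd(dX, cache$caches[[l]], blocks[[l]], B, T, H)
    grads[[l]] <- bb$grads
    dX <- bb$dX
  }
  list(dX = dX, blockGrads = grads, lnG = fin$dg, lnB = fin$db)
}

## Fixed 2-D sine-cosine positional encoding for a g x g token grid.
sincosPosEnc <- function(gridSide, dim) {
  stopifnot(dim %% 4 == 0)
  d4 <- dim %/% 4
  omega <- 1 / 10000^((seq_len(d4) - 1) / d4)
  enc1d <- function(pos) {
    ang <- outer(pos, omega)
    cbind(sin(ang), cos(ang))
  }
  ## token order is row-major: encoding rows follow (row slow, col fast)
  pr <- rep(seq_len(gridSide) - 1, each = gridSide)
  pc <- rep(seq_len(gridSide) - 1, times = gridSide)
  cbind(enc1d(pr), enc1d(pc))
}
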