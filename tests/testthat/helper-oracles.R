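# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive results by direct enumeration, never through
# the package's own computational path.

# Local mean/sd by looping over every position and mask offset with
# periodic wrap.
oracleLocalStats <- function(x, diameterPx) {
  r <- diameterPx / 2
  ri <- floor(r)
  off <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  off <- off[off$dy^2 + off$dx^2 <= r^2, ]
  nr <- nrow(x); nc <- ncol(x)
  mu <- matrix(0, nr, nc)
  sg <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- numeric(nrow(off))
      for (k in seq_len(nrow(off))) {
        ii <- ((i - 1 + off$dy[k]) %% nr) + 1
        jj <- ((j - 1 + off$dx[k]) %% nc) + 1
        vals[k] <- x[ii, jj]
      }
      mu[i, j] <- mean(vals)
      sg[i, j] <- sqrt(max(mean(vals^2) - mean(vals)^2, 0))
    }
  }
  list(mu = mu, sigma = sg)
}

# Plain Lloyd iteration from a given initialization, run to convergence.
# Empty clusters keep their previous center.
oracleLloyd <- function(X, init, iterMax = 200, tol = 1e-9) {
  C <- init
  k <- nrow(C)
  wssPath <- numeric(0)
  for (it in seq_len(iterMax)) {
    d2 <- sapply(seq_len(k), function(c_)
      rowSums((X - matrix(C[c_, ], nrow(X), ncol(X), byrow = TRUE))^2))
    assign <- apply(d2, 1, which.min)
    wssPath <- c(wssPath, sum(d2[cbind(seq_len(nrow(X)), assign)]))
    Cnew <- C
    for (c_ in seq_len(k))
      if (any(assign == c_))
        Cnew[c_, ] <- colMeans(X[assign == c_, , drop = FALSE])
    if (max(abs(Cnew - C)) < tol) { C <- Cnew; break }
    C <- Cnew
  }
  list(centers = C, wssPath = wssPath)
}

# Exhaustive overlap scoring for one refinement round: score every cluster
# of the partition against the previous particle set by its contained
# fraction |C & prev| / |C| and return the best cluster's membership
# (ties: larger intersection, then smaller cluster, then lower index).
oracleSelectCluster <- function(assign, prev, k) {
  inter <- sapply(seq_len(k), function(c_) sum(prev & assign == c_))
  sizes <- tabulate(assign, k)
  scores <- ifelse(sizes > 0, inter / sizes, -Inf)
  best <- which(scores == max(scores))
  if (length(best) > 1) best <- best[inter[best] == max(inter[best])]
  if (length(best) > 1) best <- best[sizes[best] == min(sizes[best])]
  assign == best[1]
}

# Maximum-cardinality one-to-one matching with IoU >= thr, by exhaustive
# recursion over all assignments (instances <= 6 x 6).
oracleOptimalTP <- function(iou, thr) {
  np <- nrow(iou); ng <- ncol(iou)
  bestTP <- 0
  recurse <- function(p, usedG, tp) {
    if (tp + (np - p + 1) <= bestTP) return()
    if (p > np) { bestTP <<- max(bestTP, tp); return() }
    for (g in seq_len(ng)) {
      if (!usedG[g] && iou[p, g] >= thr) {
        usedG[g] <- TRUE
        recurse(p + 1, usedG, tp + 1)
        usedG[g] <- FALSE
      }
    }
    recurse(p + 1, usedG, tp)
  }
  if (np > 0 && ng > 0) recurse(1, rep(FALSE, ng), 0)
  bestTP
}

# Direct 9-term loop for 3x3 mean smoothing with zero padding.
oracleSmooth <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      s <- 0
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) s <- s + m[ii, jj]
      }
      out[i, j] <- s / 9
    }
  }
  out
}
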