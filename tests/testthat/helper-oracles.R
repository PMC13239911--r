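# Independent reference implementations used as oracles; deliberately simple
# and kept apart from the package's code paths.

# materialise the linear operator M such that vec(fracDiff(U)) = M %*% vec(U)
# by applying it to every basis matrix
materializeOp <- function(fun, nr, nc) {
  M <- matrix(0, nr * nc, nr * nc)
  for (j in seq_len(nr * nc)) {
    E <- matrix(0, nr, nc)
    E[j] <- 1
    M[, j] <- as.vector(fun(E))
  }
  M
}

# exhaustive pair-counting Rand/ARI: iterate all pairs, count agreements,
# expected index from the hypergeometric form on the contingency margins
pairCountARI <- function(truth, pred) {
  n <- length(truth)
  a <- b <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- truth[i] == truth[j]
      sp <- pred[i] == pred[j]
      if (st && sp) a <- a + 1
      if (!st && !sp) b <- b + 1
    }
  }
  ri <- (a + b) / choose(n, 2)
  ct <- table(truth, pred)
  sumA <- sum(choose(rowSums(ct), 2))
  sumB <- sum(choose(colSums(ct), 2))
  sumIJ <- sum(choose(ct, 2))
  expIJ <- sumA * sumB / choose(n, 2)
  denom <- (sumA + sumB) / 2 - expIJ
  ari <- if (denom == 0) {
    if (all(tapply(pred, truth, function(x) length(unique(x))) == 1) &&
        all(tapply(truth, pred, function(x) length(unique(x))) == 1)) 1 else 0
  } else {
    (sumIJ - expIJ) / denom
  }
  list(ri = ri, ari = ari)
}

# from-scratch NMI via entropies of the joint distribution
entropyNMI <- function(truth, pred) {
  ct <- table(truth, pred)
  n <- sum(ct)
  p <- ct / n
  px <- rowSums(p)
  py <- colSums(p)
  H <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  mi <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
  }
  if (H(px) + H(py) == 0) return(1)
  as.numeric(2 * mi / (H(px) + H(py)))
}

# independently coded nonnegative LRR ADMM (no TV term), plain solve()
lrrBaseline <- function(X, alpha, mu, iters) {
  n <- ncol(X)
  R <- Q <- Y <- matrix(0, n, n)
  XtX <- crossprod(X)
  A <- XtX + diag(n) / mu
  for (l in seq_len(iters)) {
    R <- solve(A, XtX - Y + Q / mu)
    R[R < 0] <- 0
    s <- svd(R + mu * Y)
    d <- pmax(s$d - alpha * mu, 0)
    Q <- s$u %*% (d * t(s$v))
    Q[Q < 0] <- 0
    Y <- Y + (R - Q) / mu
  }
  list(R = R, Q = Q, Y = Y)
}

fixtureMatrix <- function(...) {
  sce <- standardFixture(...)
  list(
    X = SummarizedExperiment::assay(sce, 1),
    truth = SummarizedExperiment::colData(sce)$cluster,
    markers = S4Vectors::metadata(sce)$markers
  )
}
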