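# Independent oracles used to cross-check the package's own code paths.

# White-noise epochs with balanced labels.
whiteEpochs <- function(nPerClass = 10L, C = 4L, Tn = 60L, fs = 100,
                        seed = 1L) {
  set.seed(seed)
  n <- 2L * nPerClass
  eegEpochs(array(rnorm(n * C * Tn), c(n, C, Tn)),
            rep(1:2, each = nPerClass), fs)
}

# Reference regularized CSP on the raw channels, written independently of the
# package pipeline: plain per-class covariance averaging and a non-symmetric
# eigendecomposition of solve(B) %*% A (the package whitens with a Cholesky
# factor instead).
refCSP <- function(epochs, epsilon, m) {
  labs <- trialLabels(epochs)
  u <- sort(unique(labs))
  d <- epochData(epochs)
  C <- dim(d)[2L]
  covOf <- function(which) {
    S <- matrix(0, C, C)
    idx <- which(labs == u[which])
    for (i in idx) {
      X <- d[i, , , drop = TRUE]
      Si <- X %*% t(X)
      S <- S + Si / sum(diag(Si))
    }
    S <- S / length(idx)
    S / sum(diag(S))
  }
  S1 <- covOf(1L); S2 <- covOf(2L)
  A <- S1 + diag(epsilon, C)
  B <- S1 + S2 + diag(2 * epsilon, C)
  es <- eigen(solve(B, A))
  ord <- order(Re(es$values), decreasing = TRUE)
  vals <- Re(es$values)[ord]
  V <- Re(es$vectors)[, ord, drop = FALSE]
  V <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  sel <- c(seq_len(m), seq.int(C, C - m + 1L))
  W <- V[, sel, drop = FALSE]
  feats <- t(apply(d, 1L, function(X) {
    P <- t(W) %*% X
    log(apply(P, 1L, var))
  }))
  list(W = W, eigvals = vals[sel], features = feats)
}

# Generalized Rayleigh quotient extrema over many random unit directions.
rayleighExtrema <- function(A, B, nDirs = 1e4L) {
  D <- nrow(A)
  V <- matrix(rnorm(D * nDirs), D, nDirs)
  q <- colSums(V * (A %*% V)) / colSums(V * (B %*% V))
  c(min = min(q), max = max(q))
}

# Random symmetric positive definite matrix.
randomSPD <- function(D) {
  M <- matrix(rnorm(D * D), D, D)
  crossprod(M) + diag(0.1, D)
}

# Periodogram mass of a series inside a band.
bandMass <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2
  nb <- floor(n / 2) + 1L
  fr <- (seq_len(nb) - 1L) * fs / n
  p <- p[seq_len(nb)]
  sum(p[fr >= lo & fr <= hi]) / sum(p)
}
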