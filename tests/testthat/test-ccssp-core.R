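test_that("class covariances match the hand-computed outer product", {
  # single trial, 2 rows, samples [[1,-1],[1,1]]: X X' = [[2,0],[0,2]],
  # trace-normalized -> diag(0.5)
  d <- array(0, c(2, 2, 2))
  d[1, , ] <- rbind(c(1, -1), c(1, 1))
  d[2, , ] <- rbind(c(2, 0), c(0, 2))   # second condition, arbitrary
  e <- eegEpochs(d, c(1, 2), 100)
  S <- classCovariances(embedEpochs(e, 0L))
  expect_equal(S[[1]]@matrix, diag(0.5, 2), tolerance = 1e-14)
  expect_identical(S[[1]]@nTrialsUsed, 1L)
})

test_that("covariances are unit-trace, symmetric, and invariant to trial duplication", {
  set.seed(4)
  e <- whiteEpochs(nPerClass = 6L, C = 3L, Tn = 40L)
  S <- classCovariances(embedEpochs(e, 1L))
  for (s in S) {
    expect_equal(sum(diag(s@matrix)), 1, tolerance = 1e-12)
    expect_lt(max(abs(s@matrix - t(s@matrix))), 1e-12)
  }
  # duplicating every trial of a condition leaves its covariance unchanged
  d <- epochData(e)
  idx1 <- which(trialLabels(e) == 1L)
  d2 <- array(0, c(dim(d)[1] + length(idx1), dim(d)[2], dim(d)[3]))
  d2[seq_len(dim(d)[1]), , ] <- d
  d2[dim(d)[1] + seq_along(idx1), , ] <- d[idx1, , , drop = FALSE]
  e2 <- eegEpochs(d2, c(trialLabels(e), rep(1L, length(idx1))), 100)
  S2 <- classCovariances(embedEpochs(e2, 1L))
  expect_equal(S2[[1]]@matrix, S[[1]]@matrix, tolerance = 1e-12)
})

test_that("zero-power trials are rejected with their index", {
  d <- array(rnorm(3 * 2 * 10), c(3, 2, 10))
  d[2, , ] <- 0
  e <- eegEpochs(d, c(1, 2, 1), 100)
  expect_error(classCovariances(embedEpochs(e, 0L)), "trial 2")
})

test_that("the diagonal generalized eigenproblem has its closed-form solution", {
  g <- solveRegularizedGEVD(diag(c(0.4, 0.1)), diag(c(0.1, 0.4)), 0)
  expect_equal(g$values, c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(abs(g$vectors), diag(2), tolerance = 1e-12)
})

test_that("a dominating regularizer drives all eigenvalues to 1/2", {
  set.seed(8)
  S <- classCovariances(embedEpochs(whiteEpochs(8L, 3L, 50L), 1L))
  g <- solveRegularizedGEVD(S[[1]], S[[2]], 1e6)
  expect_equal(g$values, rep(0.5, 9), tolerance = 1e-5)
})

test_that("eigenvalues lie in (0,1) and swapping class roles complements the spectrum", {
  set.seed(12)
  for (rep in 1:5) {
    D <- sample(2:6, 1)
    S1 <- randomSPD(D); S1 <- S1 / sum(diag(S1))
    S2 <- randomSPD(D); S2 <- S2 / sum(diag(S2))
    g12 <- solveRegularizedGEVD(S1, S2, 1e-3)
    expect_true(all(g12$values > 0 & g12$values < 1))
    g21 <- solveRegularizedGEVD(S2, S1, 1e-3)
    expect_equal(g12$values, rev(1 - g21$values), tolerance = 1e-10)
  }
})

test_that("a singular composite matrix without regularization is a diagnosed failure", {
  v <- c(1, 2, 3)
  S <- outer(v, v); S <- S / sum(diag(S))   # rank one
  expect_error(solveRegularizedGEVD(S, S, 0), "singular")
  expect_error(solveRegularizedGEVD(S, S, -1), "non-negative")
  expect_error(solveRegularizedGEVD(S, matrix(rnorm(9), 3), 1e-5),
               "not symmetric")
})

test_that("solver extrema match brute-force Rayleigh quotients on random SPD pairs", {
  set.seed(14)
  for (rep in 1:10) {
    D <- sample(2:6, 1)
    S1 <- randomSPD(D); S1 <- S1 / sum(diag(S1))
    S2 <- randomSPD(D); S2 <- S2 / sum(diag(S2))
    eps <- 1e-4
    g <- solveRegularizedGEVD(S1, S2, eps)
    A <- S1 + diag(eps, D); B <- S1 + S2 + diag(2 * eps, D)
    ext <- rayleighExtrema(A, B, 1e4L)
    # the random search must never beat the solver's extrema
    expect_lt(ext["max"] - g$values[1], 1e-3 * g$values[1])
    expect_lt(g$values[D] - ext["min"], 1e-3 * g$values[D])
    # and the solver's eigenvector attains its reported eigenvalue
    w1 <- g$vectors[, 1]; wD <- g$vectors[, D]
    expect_equal(drop(crossprod(w1, A %*% w1) / crossprod(w1, B %*% w1)),
                 g$values[1], tolerance = 1e-10)
    expect_equal(drop(crossprod(wD, A %*% wD) / crossprod(wD, B %*% wD)),
                 g$values[D], tolerance = 1e-10)
  }
})

test_that("fit orders eigenvalues per the pair convention and validates m", {
  e <- whiteEpochs(10L, 4L, 60L, seed = 2L)
  mod <- fitCCSSP(e, k = 1L, epsilon = 1e-5, m = 2L)
  ev <- eigenValues(mod)
  expect_length(ev, 4L)
  expect_true(ev[1] >= ev[2])            # m largest, descending
  expect_true(ev[3] <= ev[4])            # m smallest, ascending
  expect_true(all(ev > 0 & ev < 1))
  W <- filterWeights(mod)
  expect_equal(colSums(W^2), rep(1, 4), tolerance = 1e-10)
  # sign convention: largest-magnitude entry positive
  for (j in 1:4) expect_gt(W[which.max(abs(W[, j])), j], 0)
  expect_error(fitCCSSP(e, k = 0L, epsilon = 1e-5, m = 3L), "2m")
})

test_that("k = 0 fit reproduces an independently implemented regularized CSP", {
  for (seed in 1:5) {
    e <- whiteEpochs(12L, 4L, 60L, seed = seed)
    mod <- fitCCSSP(e, k = 0L, epsilon = 1e-5, m = 2L)
    ref <- refCSP(e, epsilon = 1e-5, m = 2L)
    expect_lt(max(abs(filterWeights(mod) - ref$W)), 1e-8)
    expect_lt(max(abs(extractFeatures(mod, e) - ref$features)), 1e-10)
  }
})

test_that("channel permutation permutes each delay block of every filter identically", {
  set.seed(31)
  suite <- defaultBenchmarkSuite(3L)
  e <- generateEpochs(suite[[2]]$spec)$epochs
  perm <- c(4, 1, 6, 2, 5, 3)
  dPerm <- epochData(e)[, perm, , drop = FALSE]
  ePerm <- eegEpochs(dPerm, trialLabels(e), samplingRate(e))
  k <- 2L
  m1 <- fitCCSSP(e, k = k, epsilon = 1e-5, m = 1L)
  m2 <- fitCCSSP(ePerm, k = k, epsilon = 1e-5, m = 1L)
  expect_equal(eigenValues(m1), eigenValues(m2), tolerance = 1e-8)
  for (j in 1:2) {
    s1 <- splitSpatialFilters(m1, j)
    s2 <- splitSpatialFilters(m2, j)
    # row d of the permuted fit equals row d of the original, channels permuted
    expect_equal(unname(s2), unname(s1[, perm]), tolerance = 1e-6)
  }
})

test_that("regularization monotonically pulls eigenvalues toward 1/2", {
  set.seed(16)
  S <- classCovariances(embedEpochs(whiteEpochs(8L, 3L, 50L, seed = 16L), 2L))
  dev <- vapply(10^seq(-6, 0), function(eps) {
    max(abs(solveRegularizedGEVD(S[[1]], S[[2]], eps)$values - 0.5))
  }, numeric(1))
  expect_true(all(diff(dev) <= 1e-12))
})

test_that("log-variance features obey the scaling identity and sampling error bound", {
  set.seed(18)
  e <- whiteEpochs(5L, 3L, 80L, seed = 18L)
  mod <- fitCCSSP(e, k = 1L, epsilon = 1e-5, m = 2L)
  f1 <- extractFeatures(mod, e)
  d <- epochData(e); d[2, , ] <- 3 * d[2, , ]
  f2 <- extractFeatures(mod, eegEpochs(d, trialLabels(e), 100))
  expect_equal(unname(f2[2, ] - f1[2, ]), rep(2 * log(3), 4), tolerance = 1e-10)
  expect_equal(f2[-2, ], f1[-2, ], tolerance = 1e-12)

  # unit filter on one raw channel, white noise with variance 4
  Tn <- 500L
  set.seed(19)
  dn <- array(rnorm(2 * 2 * Tn, sd = 2), c(2, 2, Tn))
  en <- eegEpochs(dn, c(1, 2), 100)
  modU <- fitCCSSP(en, k = 0L, epsilon = 1e-5, m = 1L)
  modU@W <- cbind(c(1, 0), c(0, 1))     # overwrite with unit filters
  f <- extractFeatures(modU, en)
  expect_lt(abs(f[1, 1] - log(4)), 3 * sqrt(2 / (Tn - 1)))

  # zero trial errors instead of returning -Inf
  dz <- dn; dz[1, , ] <- 0
  ez <- eegEpochs(dz, c(1, 2), 100)
  expect_error(extractFeatures(modU, ez), "zero variance")

  # mismatched geometry is rejected
  e3 <- whiteEpochs(5L, 4L, 80L)
  expect_error(extractFeatures(mod, e3), "channel count")
})

test_that("normalized feature variant sums variances to one per trial", {
  e <- whiteEpochs(6L, 3L, 60L, seed = 22L)
  mod <- fitCCSSP(e, k = 1L, epsilon = 1e-5, m = 2L)
  fn <- extractFeatures(mod, e, normalize = TRUE)
  expect_equal(rowSums(exp(fn)), rep(1, nTrials(e)), tolerance = 1e-10)
})
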