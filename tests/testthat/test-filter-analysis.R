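# A fitted model on the channel-specific-band scenario, reused across tests.
fittedScenarioB <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generateEpochs(defaultBenchmarkSuite(7L)[[2]]$spec)
      cache <<- list(epochs = gen$epochs,
                     model = fitCCSSP(gen$epochs, k = 5L, epsilon = 1e-5, m = 2L))
    }
    cache
  }
})

test_that("splitting a k=5 filter yields 11 per-delay spatial filters that reconstruct it", {
  model <- fittedScenarioB()$model
  sp <- splitSpatialFilters(model, 1L)
  expect_identical(dim(sp), c(11L, 6L))
  expect_identical(rownames(sp), as.character(-5:5))
  # concatenating the slices in delay order reconstructs the column exactly
  expect_identical(as.numeric(t(sp)), filterWeights(model)[, 1])
  expect_error(splitSpatialFilters(model, 99L), "filterId")
})

test_that("k = 0 splitting returns the column itself as a single spatial filter", {
  e <- whiteEpochs(8L, 3L, 40L, seed = 6L)
  model <- fitCCSSP(e, k = 0L, epsilon = 1e-5, m = 1L)
  sp <- splitSpatialFilters(model, 1L)
  expect_identical(dim(sp), c(1L, 3L))
  expect_identical(as.numeric(sp), filterWeights(model)[, 1])
})

test_that("channel FIR taps are the column entries across delay blocks", {
  model <- fittedScenarioB()$model
  # unit-vector column on (delay 0, channel 2): delta taps there, zero elsewhere
  D <- nrow(filterWeights(model))
  unitModel <- model
  w <- numeric(D); w[rowIndex(0L, 2L, 5L, 6L)] <- 1
  unitModel@W <- cbind(w, filterWeights(model)[, 2])
  fir2 <- channelFIR(unitModel, 1L, 2L)
  expect_equal(fir2@taps, c(rep(0, 5), 1, rep(0, 5)))
  expect_equal(channelFIR(unitModel, 1L, 1L)@taps, rep(0, 11))

  # norm partition: squared taps over all channels sum to 1 per column
  for (j in seq_len(ncol(filterWeights(model)))) {
    tot <- sum(vapply(seq_len(6L), function(c)
      sum(channelFIR(model, j, c)@taps^2), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-10)
  }

  # on a fitted model the FIR filters are genuinely channel-specific
  taps <- vapply(seq_len(6L), function(c) channelFIR(model, 1L, c)@taps,
                 numeric(11L))
  dist <- max(dist(t(taps)))
  expect_gt(dist, 0)

  # channels addressable by name
  expect_identical(channelFIR(model, 1L, channelNames(model)[1]),
                   channelFIR(model, 1L, 1L))
})

test_that("frequency response matches closed forms", {
  # delta at delay 0 is all-pass
  fr <- frequencyResponse(c(0, 1, 0), fs = 100, nPoints = 64L)
  expect_equal(fr@magnitude, rep(1, 64), tolerance = 1e-12)
  # symmetric two-tap filter: |H(f)| = |cos(2 pi f / fs)|
  fr2 <- frequencyResponse(c(0.5, 0, 0.5), fs = 100, nPoints = 101L)
  expect_equal(fr2@magnitude, abs(cos(2 * pi * fr2@freqs / 100)),
               tolerance = 1e-12)
  # DC gain equals |sum of taps|
  set.seed(33)
  taps <- rnorm(7)
  fr3 <- frequencyResponse(taps, fs = 250)
  expect_equal(fr3@magnitude[1], abs(sum(taps)), tolerance = 1e-12)
  # linearity in the taps
  t1 <- rnorm(5); t2 <- rnorm(5)
  H12 <- frequencyResponse(2 * t1 - t2, fs = 100, nPoints = 32L)@H
  expect_equal(H12, 2 * frequencyResponse(t1, 100, 32L)@H -
                     frequencyResponse(t2, 100, 32L)@H, tolerance = 1e-12)
  expect_error(frequencyResponse(t1, fs = -1), "fs")
  expect_error(frequencyResponse(rnorm(4), fs = 100), "odd")
})

test_that("relative power concentrates on a pure tone and always sums to one", {
  fs <- 100
  x <- sin(2 * pi * 10 * (0:(fs - 1)) / fs)
  ps <- relativePower(x, fs)
  expect_equal(sum(ps@relativePower), 1, tolerance = 1e-12)
  expect_gt(ps@relativePower[which.min(abs(ps@freqs - 10))], 0.9)
  expect_error(relativePower(numeric(200), fs), "all-zero")
  expect_error(relativePower(rnorm(4), fs), "too short")
})

test_that("filtered ERPs have the valid-region length and the planted power contrast", {
  suite <- defaultBenchmarkSuite(5L)
  gen <- generateEpochs(suite[[3]]$spec)
  model <- fitCCSSP(gen$epochs, k = 5L, epsilon = 1e-5, m = 2L)
  erp <- filteredERP(model, gen$epochs, 1L)
  expect_identical(ncol(erp), nSamples(gen$epochs) - 10L)
  # target (condition 1) mean carries more power under the leading filter
  expect_gt(var(erp["cond1", ]), var(erp["cond2", ]))

  # linearity: zero input gives a zero ERP
  zero <- eegEpochs(array(0, c(2, 8, 125)), c(1, 2), 250)
  expect_equal(filteredERP(model, zero, 1L), erp * 0)
})

test_that("a low-pass-like learned filter shifts ERP mass toward low frequencies", {
  suite <- defaultBenchmarkSuite(5L)
  gen <- generateEpochs(suite[[3]]$spec)
  model <- fitCCSSP(gen$epochs, k = 5L, epsilon = 1e-5, m = 2L)
  fs <- samplingRate(gen$epochs)
  # raw target ERP on the most loaded channel vs the filtered target ERP
  tIdx <- which(trialLabels(gen$epochs) == 1L)
  raw <- apply(epochData(gen$epochs)[tIdx, 5L, ], 2L, mean)
  filt <- filteredERP(model, gen$epochs, 1L)["cond1", ]
  highMass <- function(x) {
    ps <- relativePower(x, fs)
    sum(ps@relativePower[ps@freqs > 10])
  }
  expect_lt(highMass(filt), highMass(raw[6:120]))
})
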