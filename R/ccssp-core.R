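## Core method: class covariances on the augmented space, the regularized
## generalized eigendecomposition, filter-pair selection and log-variance
## features.

#' Per-condition covariance matrices on the augmented space
#'
#' For each trial computes the scatter `X %*% t(X)` of its augmented matrix,
#' divides by its trace, then averages across the condition's trials and
#' renormalizes the mean to unit trace. Per-trial trace normalization equalizes
#' trial power before averaging (standard CSP practice).
#'
#' @param aug an [AugmentedEpochs-class] object carrying both conditions.
#' @return A list of two [ClassCovariance-class] objects (condition 1 = the
#'   smaller stored label, condition 2 = the larger).
#' @export
classCovariances <- function(aug) {
  conds <- asConditions(aug@labels)
  D <- dim(aug@data)[2L]
  lapply(1:2, function(cond) {
    idx <- which(conds == cond)
    if (!length(idx)) stopData("condition ", cond, " has zero trials")
    S <- matrix(0, D, D)
    for (i in idx) {
      X <- aug@data[i, , , drop = TRUE]
      if (is.null(dim(X))) X <- matrix(X, nrow = D)
      Si <- tcrossprod(X)
      tr <- sum(diag(Si))
      if (tr <= 0)
        stopNumerical("trial ", i, " has zero total power (trace 0)")
      S <- S + Si / tr
    }
    S <- S / length(idx)
    S <- (S + t(S)) / 2
    S <- S / sum(diag(S))
    new("ClassCovariance", matrix = S, condition = as.integer(cond),
        nTrialsUsed = length(idx))
  })
}

#' Solve the regularized generalized eigenvalue problem
#'
#' Solves `(S1 + eps I) w = lambda (S1 + S2 + 2 eps I) w`. With `eps > 0` the
#' right-hand matrix is positive definite, so the problem is well posed, all
#' eigenvalues are real and lie strictly in (0, 1), and swapping the roles of
#' the two classes maps the spectrum to its reversed complement `1 - lambda`.
#' On the high-dimensional augmented space the composite matrix is easily
#' singular when trials are few (the delay copies multiply the "channels"),
#' which is exactly what the regularizer guards against.
#'
#' @param S1,S2 [ClassCovariance-class] objects (or plain symmetric matrices)
#'   of matching dimension.
#' @param epsilon non-negative regularization scalar; 0 is allowed only for
#'   well-conditioned inputs.
#' @return A list with `values` (descending eigenvalues) and `vectors`
#'   (columns aligned with `values`, unit norm, largest-magnitude entry
#'   positive).
#' @export
solveRegularizedGEVD <- function(S1, S2, epsilon) {
  if (is(S1, "ClassCovariance")) S1 <- S1@matrix
  if (is(S2, "ClassCovariance")) S2 <- S2@matrix
  if (!all(dim(S1) == dim(S2)))
    stopUsage("covariance dimensions do not match")
  if (max(abs(S1 - t(S1))) > 1e-8 || max(abs(S2 - t(S2))) > 1e-8)
    stopData("covariance input is not symmetric")
  if (epsilon < 0) stopUsage("epsilon must be non-negative")
  D <- nrow(S1)
  A <- S1 + diag(epsilon, D)
  B <- S1 + S2 + diag(2 * epsilon, D)
  U <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(U) || min(diag(U)) < sqrt(.Machine$double.eps * sum(diag(B))))
    stopNumerical("composite covariance matrix is singular or near-singular; ",
                  "regularize with epsilon > 0 (the augmented 'channels' can ",
                  "outnumber the samples)")
  Uinv <- backsolve(U, diag(D))
  M <- crossprod(Uinv, A %*% Uinv)
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)      # values already descending
  V <- Uinv %*% es$vectors
  nrm <- sqrt(colSums(V^2))
  V <- sweep(V, 2L, nrm, "/")
  for (j in seq_len(D)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(values = es$values, vectors = V)
}

#' Fit the spatial-spectral filter bank
#'
#' The full pipeline: delay-embed the epochs with half-order `k`, estimate the
#' two class covariances, solve the regularized generalized eigenvalue
#' problem, and keep the `m` columns with the largest eigenvalues (variance
#' maximal for condition 1) plus the `m` with the smallest (variance maximal
#' for condition 2). `k = 0` reduces the method to regularized conventional
#' CSP on the raw channels.
#'
#' @param epochs training [EEGEpochs-class] with both classes present.
#' @param k FIR half-order (default 5, i.e. 11-tap filters).
#' @param epsilon regularization scalar (default `1e-5`).
#' @param m filter pairs to keep (default 3; 2 is typical for event-related
#'   potential detection).
#' @return A [SpatialSpectralModel-class].
#' @export
fitCCSSP <- function(epochs, k = 5L, epsilon = 1e-5, m = 3L) {
  k <- as.integer(k); m <- as.integer(m)
  if (m < 1L) stopUsage("m must be >= 1")
  D <- nChannels(epochs) * (2L * k + 1L)
  if (2L * m > D)
    stopUsage("2m = ", 2L * m, " filters requested but the augmented space ",
              "has only D = ", D, " dimensions")
  aug <- embedEpochs(epochs, k)
  S <- classCovariances(aug)
  g <- solveRegularizedGEVD(S[[1L]], S[[2L]], epsilon)
  top <- seq_len(m)                      # m largest, descending
  bot <- seq.int(D, D - m + 1L)          # m smallest, ascending
  sel <- c(top, bot)
  new("SpatialSpectralModel",
      W = g$vectors[, sel, drop = FALSE],
      eigvals = g$values[sel],
      k = k, epsilon = as.numeric(epsilon), m = m,
      nChannels = nChannels(epochs),
      channelNames = channelNames(epochs),
      fs = samplingRate(epochs))
}

#' Log-variance features
#'
#' Delay-embeds each trial with the model's `k`, projects it onto every filter
#' column, and takes the natural log of the sample variance of each projected
#' series. Scaling a trial by `c` shifts all of its features by `2 log(c)`.
#' Features are not normalized across the selected filters; set
#' `normalize = TRUE` for the variance-share variant
#' (`log(var_j / sum_j var_j)`).
#'
#' @param model a fitted [SpatialSpectralModel-class].
#' @param epochs [EEGEpochs-class] with the model's channel count and
#'   sampling rate.
#' @param normalize use normalized variances (default `FALSE`).
#' @return A numeric matrix `[n_trials, 2m]`; column names are the filter ids.
#' @export
extractFeatures <- function(model, epochs, normalize = FALSE) {
  if (nChannels(epochs) != model@nChannels)
    stopData("channel count mismatch: model has ", model@nChannels,
             ", epochs have ", nChannels(epochs))
  if (abs(samplingRate(epochs) - model@fs) > 1e-9)
    stopData("sampling rate mismatch: model ", model@fs, " Hz, epochs ",
             samplingRate(epochs), " Hz")
  aug <- embedEpochs(epochs, model@k)
  nT <- nTrials(aug)
  nF <- ncol(model@W)
  V <- matrix(0, nT, nF)
  for (i in seq_len(nT)) {
    X <- aug@data[i, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = nrow(model@W))
    P <- crossprod(model@W, X)           # [2m x T'] projected series
    v <- apply(P, 1L, stats::var)
    zero <- which(v <= 0)
    if (length(zero))
      stopNumerical("projected series has zero variance (trial ", i,
                    ", filter ", zero[1L], "); degenerate input")
    V[i, ] <- v
  }
  F <- if (normalize) log(V / rowSums(V)) else log(V)
  colnames(F) <- paste0("f", seq_len(nF))
  F
}
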