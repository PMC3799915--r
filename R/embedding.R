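## Time-delay embedding: stacking time-shifted copies of every channel so that
## an FIR filter per channel becomes a spatial weighting over the augmented
## rows. Only the valid region (samples where all 2k+1 shifts exist) is kept;
## zero-padding would inject spurious transients into the covariance
## estimates, and 2k << T in all intended uses.

#' Augmented-space row index for a (delay, channel) pair
#'
#' Block layout is delay-major: all channels of delay `-k` first. The row of
#' delay `i` and channel `c` (1-based) is `(i + k) * n_channels + c`; the map
#' is a bijection onto `1..n_channels*(2k+1)`.
#'
#' @param delay delay index in `-k..k`.
#' @param channel channel index in `1..nChannels`.
#' @param k FIR half-order.
#' @param nChannels channel count.
#' @return The 1-based row index.
#' @export
rowIndex <- function(delay, channel, k, nChannels) {
  if (any(delay < -k | delay > k))
    stopUsage("delay out of range [-k, k]: ", paste(delay, collapse = ", "))
  if (any(channel < 1L | channel > nChannels))
    stopUsage("channel out of range [1, ", nChannels, "]")
  (delay + k) * nChannels + channel
}

#' Delay-embed epochs
#'
#' Builds the augmented representation: for every trial, row
#' `rowIndex(i, c, k, C)` at sample `t` equals original channel `c` at sample
#' `t + k + i`, for delays `i` in `-k..k`. With `k = 0` the data are returned
#' unchanged (`D = C`, `T' = T`) — the conventional CSP special case.
#'
#' @param epochs an [EEGEpochs-class] object with `n_samples > 2k`.
#' @param k non-negative integer FIR half-order; the embedded FIR filters have
#'   `2k+1` taps on symmetric support `-k..k`.
#' @return An [AugmentedEpochs-class] object with
#'   `D = n_channels * (2k+1)` rows and `T' = n_samples - 2k` samples.
#' @export
embedEpochs <- function(epochs, k) {
  k <- as.integer(k)
  if (k < 0L) stopUsage("k must be non-negative")
  Tn <- nSamples(epochs)
  if (2L * k >= Tn)
    stopUsage("epoch too short for k=", k,
              ": need n_samples > 2k, i.e. at least ", 2L * k + 1L,
              " samples, got ", Tn)
  C <- nChannels(epochs)
  Tp <- Tn - 2L * k
  D <- C * (2L * k + 1L)
  nT <- nTrials(epochs)
  out <- array(0, c(nT, D, Tp))
  for (i in -k:k) {
    rows <- rowIndex(i, seq_len(C), k, C)
    ## valid-region sample t (1..T') maps to original sample t + k + i
    out[, rows, ] <- epochs@data[, , (k + i + 1L):(k + i + Tp), drop = FALSE]
  }
  new("AugmentedEpochs", data = out, k = k, nChannels = C,
      labels = epochs@labels, fs = epochs@fs, channelNames = epochs@channelNames)
}
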