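## Interpretability analyses of fitted spatial-FIR filters: per-delay spatial
## filters, per-channel FIR taps and frequency responses, relative power
## spectra, and class-averaged filtered waveforms.

#' Split a spatial-FIR filter into per-delay spatial filters
#'
#' A model column is a weight per (delay, channel) row; slicing it by delay
#' block yields `2k+1` ordinary spatial filters, one acting on each
#' time-shifted copy of the data. Concatenating the rows in delay order
#' reconstructs the column exactly.
#'
#' @param model a [SpatialSpectralModel-class].
#' @param filterId column index in `1..2m`.
#' @return A numeric matrix `[2k+1, n_channels]`; row `i` is the spatial
#'   filter of delay `-k + i - 1`, rownames give the delay, colnames the
#'   channels.
#' @export
splitSpatialFilters <- function(model, filterId) {
  filterId <- as.integer(filterId)
  if (filterId < 1L || filterId > ncol(model@W))
    stopUsage("filterId out of range [1, ", ncol(model@W), "]")
  k <- model@k; C <- model@nChannels
  w <- model@W[, filterId]
  out <- matrix(w, nrow = 2L * k + 1L, ncol = C, byrow = TRUE)
  rownames(out) <- as.character(-k:k)
  colnames(out) <- model@channelNames
  out
}

#' Channel-specific FIR taps of a model column
#'
#' Tap `i` (delay `-k..k`) of channel `c` is the column's entry at
#' `rowIndex(i, c, k, C)`: the FIR filter the column applies to that channel
#' before spatial summation. Across a column the squared taps of all channels
#' sum to one (the unit-norm invariant redistributed).
#'
#' @param model a [SpatialSpectralModel-class].
#' @param filterId column index.
#' @param channel channel index (1-based) or channel name.
#' @return A [FIRCoefficients-class] object.
#' @export
channelFIR <- function(model, filterId, channel) {
  filterId <- as.integer(filterId)
  if (filterId < 1L || filterId > ncol(model@W))
    stopUsage("filterId out of range [1, ", ncol(model@W), "]")
  if (is.character(channel))
    channel <- match(channel, model@channelNames)
  channel <- as.integer(channel)
  if (is.na(channel) || channel < 1L || channel > model@nChannels)
    stopUsage("unknown channel")
  k <- model@k
  rows <- rowIndex(-k:k, channel, k, model@nChannels)
  new("FIRCoefficients", taps = model@W[rows, filterId],
      channel = channel, filterId = filterId, k = k)
}

#' Frequency response of FIR taps
#'
#' Evaluates `H(f) = sum_{i=-k}^{k} taps[i] exp(-1i 2 pi f i / fs)` on a
#' uniform grid over `[0, fs/2]`. The symmetric non-causal support makes `H`
#' complex in general; the magnitude is what filter-inspection plots show.
#'
#' @param fir a [FIRCoefficients-class] object (or a plain numeric tap vector
#'   of odd length, delay order `-k..k`).
#' @param fs sampling rate in Hz.
#' @param nPoints grid size (default 256, minimum 2).
#' @return A [FrequencyResponse-class] object.
#' @export
frequencyResponse <- function(fir, fs, nPoints = 256L) {
  if (is(fir, "FIRCoefficients")) taps <- fir@taps else taps <- as.numeric(fir)
  if (length(taps) %% 2L != 1L)
    stopUsage("taps must have odd length 2k+1")
  if (fs <= 0) stopUsage("fs must be positive")
  if (nPoints < 2L) stopUsage("nPoints must be >= 2")
  k <- (length(taps) - 1L) %/% 2L
  freqs <- seq(0, fs / 2, length.out = nPoints)
  H <- vapply(freqs, function(f)
    sum(taps * exp(-1i * 2 * pi * f * (-k:k) / fs)), complex(1L))
  new("FrequencyResponse", freqs = freqs, H = H, magnitude = Mod(H))
}

#' Relative power spectrum of a series
#'
#' Raw periodogram (no tapering or segment averaging: class-averaged
#' event-related potentials are short, and one spectrum per condition is
#' wanted) normalized to total mass one.
#'
#' @param x numeric series of length >= 8, e.g. a class-averaged
#'   event-related potential on one (virtual) channel.
#' @param fs sampling rate in Hz.
#' @return A [PowerSpectrum-class] object.
#' @export
relativePower <- function(x, fs) {
  x <- as.numeric(x)
  if (length(x) < 8L) stopUsage("series too short (need length >= 8)")
  if (all(x == 0)) stopData("all-zero signal has no power spectrum")
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  nb <- floor(n / 2) + 1L
  p <- p[seq_len(nb)]
  freqs <- (seq_len(nb) - 1L) * fs / n
  new("PowerSpectrum", freqs = freqs, relativePower = p / sum(p))
}

#' Class-averaged filtered waveforms
#'
#' Projects every trial on one model column after delay embedding and averages
#' the projected series within each condition: the filtered target/non-target
#' event-related potentials whose variance contrast the selected filter
#' maximizes.
#'
#' @param model a [SpatialSpectralModel-class].
#' @param epochs [EEGEpochs-class] with both conditions present.
#' @param filterId column index.
#' @return A numeric matrix `[2, n_samples - 2k]`, rows named `cond1`/`cond2`.
#' @export
filteredERP <- function(model, epochs, filterId) {
  filterId <- as.integer(filterId)
  if (filterId < 1L || filterId > ncol(model@W))
    stopUsage("filterId out of range [1, ", ncol(model@W), "]")
  aug <- embedEpochs(epochs, model@k)
  conds <- asConditions(aug@labels)
  w <- model@W[, filterId]
  Tp <- dim(aug@data)[3L]
  out <- matrix(0, 2L, Tp, dimnames = list(c("cond1", "cond2"), NULL))
  for (cond in 1:2) {
    idx <- which(conds == cond)
    if (!length(idx)) stopData("condition ", cond, " has zero trials")
    acc <- numeric(Tp)
    for (i in idx) {
      X <- aug@data[i, , , drop = TRUE]
      if (is.null(dim(X))) X <- matrix(X, nrow = length(w))
      acc <- acc + drop(crossprod(w, X))
    }
    out[cond, ] <- acc / length(idx)
  }
  out
}
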