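#' @import methods
NULL

#' Labeled epoched EEG
#'
#' Container for epoched multichannel EEG: a numeric tensor of
#' trials x channels x samples (microvolts, units treated as opaque), one
#' integer condition label per trial, the sampling rate and ordered channel
#' names. All downstream matrices use the channel order of this object.
#'
#' Labels are stored as given (any two integer values); the canonical mapping
#' "smaller label -> condition 1" is applied at fit time, so files produced by
#' other tools need no relabeling.
#'
#' @slot data numeric array `[n_trials, n_channels, n_samples]`, finite.
#' @slot labels integer vector, one per trial, at most two distinct values.
#' @slot fs sampling rate in Hz, positive scalar.
#' @slot channelNames character vector of length `n_channels`.
#'
#' @seealso [eegEpochs()] for construction, [readEpochs()]/[writeEpochs()]
#'   for the HDF5 container.
#' @export
setClass("EEGEpochs", representation(
  data = "array",
  labels = "integer",
  fs = "numeric",
  channelNames = "character"
))

setValidity("EEGEpochs", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("data: must be a 3-D array [trials x channels x samples]")
  if (!is.numeric(d) || anyNA(d) || any(!is.finite(d)))
    return("data: contains non-finite values")
  if (length(object@labels) != dim(d)[1L])
    return("labels: length must equal the number of trials")
  if (length(unique(object@labels)) > 2L)
    return("labels: at most two distinct values allowed")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs: must be a positive scalar")
  if (length(object@channelNames) != dim(d)[2L])
    return("channelNames: length must equal the number of channels")
  TRUE
})

#' Continuous (pre-segmentation) EEG recording
#'
#' A channels x samples matrix with sampling rate and channel names; the input
#' to continuous-domain filtering and to [segmentEpochs()].
#'
#' @slot data numeric matrix `[n_channels, n_samples]`, finite.
#' @slot fs sampling rate in Hz, positive scalar.
#' @slot channelNames character vector, one per channel.
#' @export
setClass("ContinuousEEG", representation(
  data = "matrix",
  fs = "numeric",
  channelNames = "character"
))

setValidity("ContinuousEEG", function(object) {
  if (!is.numeric(object@data) || anyNA(object@data) || any(!is.finite(object@data)))
    return("data: contains non-finite values")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs: must be a positive scalar")
  if (length(object@channelNames) != nrow(object@data))
    return("channelNames: length must equal the number of channels (rows)")
  TRUE
})

#' Delay-embedded epochs
#'
#' Epochs after time-delay embedding with FIR half-order `k`: each trial's
#' channel matrix is replaced by a `D x T'` matrix with
#' `D = n_channels * (2k+1)` rows and `T' = n_samples - 2k` samples (only the
#' valid region where all shifts exist is kept; no padding). Block layout is
#' delay-major: all channels of delay `-k` first, then delay `-k+1`, ...,
#' then `+k`; see [rowIndex()].
#'
#' @slot data numeric array `[n_trials, D, T']`.
#' @slot k non-negative integer FIR half-order.
#' @slot nChannels original channel count.
#' @slot labels per-trial labels carried over from the source epochs.
#' @slot fs sampling rate in Hz.
#' @slot channelNames original channel names.
#' @export
setClass("AugmentedEpochs", representation(
  data = "array",
  k = "integer",
  nChannels = "integer",
  labels = "integer",
  fs = "numeric",
  channelNames = "character"
))

setValidity("AugmentedEpochs", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data: must be a 3-D array")
  if (object@k < 0L) return("k: must be non-negative")
  if (d[2L] != object@nChannels * (2L * object@k + 1L))
    return("data: row count must equal nChannels * (2k+1)")
  if (d[3L] < 1L) return("data: no valid samples left after embedding")
  if (length(object@labels) != d[1L])
    return("labels: length must equal the number of trials")
  TRUE
})

#' Per-condition covariance on the augmented space
#'
#' Trace-normalized symmetric positive semidefinite matrix: per trial the
#' scatter of the embedded data is divided by its trace, then averaged over
#' the condition's trials and renormalized to unit trace.
#'
#' @slot matrix symmetric `D x D` matrix with trace 1.
#' @slot condition condition index, 1 or 2.
#' @slot nTrialsUsed number of trials averaged.
#' @export
setClass("ClassCovariance", representation(
  matrix = "matrix",
  condition = "integer",
  nTrialsUsed = "integer"
))

setValidity("ClassCovariance", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix: must be square")
  if (max(abs(m - t(m))) > 1e-12) return("matrix: not symmetric (tolerance 1e-12)")
  tr <- sum(diag(m))
  if (abs(tr - 1) > 1e-12) return("matrix: trace must be 1 (normalized)")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * tr) return("matrix: not positive semidefinite")
  if (!(object@condition %in% c(1L, 2L))) return("condition: must be 1 or 2")
  TRUE
})

#' Fitted spatial-spectral filter bank
#'
#' The result of solving the regularized generalized eigenvalue problem on the
#' augmented space and keeping the `m` most discriminative filter pairs.
#' Column `j` of `W` is one spatial-FIR filter: a vector over the
#' channel-by-delay rows that splits into `2k+1` per-delay spatial filters
#' ([splitSpatialFilters()]) or, viewed per channel, into channel-specific FIR
#' taps ([channelFIR()]).
#'
#' @slot W numeric matrix `[D, 2m]`, unit-norm columns, sign fixed so each
#'   column's largest-magnitude entry is positive. Columns `1..m` carry the
#'   `m` largest eigenvalues in descending order; columns `m+1..2m` the `m`
#'   smallest in ascending order.
#' @slot eigvals eigenvalues aligned with the columns, each strictly in (0,1)
#'   when `epsilon > 0`.
#' @slot k FIR half-order used for embedding.
#' @slot epsilon identity-matrix regularization scalar.
#' @slot m number of filter pairs retained.
#' @slot nChannels,channelNames,fs metadata of the training epochs.
#' @export
setClass("SpatialSpectralModel", representation(
  W = "matrix",
  eigvals = "numeric",
  k = "integer",
  epsilon = "numeric",
  m = "integer",
  nChannels = "integer",
  channelNames = "character",
  fs = "numeric"
))

setValidity("SpatialSpectralModel", function(object) {
  m <- object@m
  if (ncol(object@W) != 2L * m) return("W: must have 2m columns")
  if (nrow(object@W) != object@nChannels * (2L * object@k + 1L))
    return("W: row count must equal nChannels * (2k+1)")
  if (length(object@eigvals) != 2L * m)
    return("eigvals: must align with the 2m columns")
  if (m > 1L) {
    if (any(diff(object@eigvals[seq_len(m)]) > 0))
      return("eigvals: first m must be descending")
    if (any(diff(object@eigvals[m + seq_len(m)]) < 0))
      return("eigvals: last m must be ascending")
  }
  if (object@epsilon > 0 &&
      (any(object@eigvals <= 0) || any(object@eigvals >= 1)))
    return("eigvals: must lie strictly in (0,1) when epsilon > 0")
  nrm <- sqrt(colSums(object@W^2))
  if (any(abs(nrm - 1) > 1e-8)) return("W: columns must have unit norm")
  TRUE
})

#' Per-channel FIR filter taps
#'
#' The `2k+1` taps of the FIR filter that one model column applies to one
#' channel: tap `i` (delay index from `-k` to `+k`) is the column's entry in
#' the delay-`i` block at that channel.
#'
#' @slot taps numeric vector of length `2k+1`, tap order delay `-k` to `+k`.
#' @slot channel channel index (1-based).
#' @slot filterId model column index.
#' @slot k FIR half-order.
#' @export
setClass("FIRCoefficients", representation(
  taps = "numeric",
  channel = "integer",
  filterId = "integer",
  k = "integer"
))

setValidity("FIRCoefficients", function(object) {
  if (length(object@taps) != 2L * object@k + 1L)
    return("taps: length must be 2k+1")
  if (any(!is.finite(object@taps))) return("taps: must be finite")
  TRUE
})

#' Frequency response of an FIR filter
#'
#' Complex response `H(f) = sum_i taps[i] exp(-j 2 pi f i / fs)` evaluated on
#' an ascending grid over `[0, fs/2]`; the symmetric non-causal support makes
#' `H` complex in general, so magnitude is carried alongside.
#'
#' @slot freqs frequency grid in Hz.
#' @slot H complex response values.
#' @slot magnitude `abs(H)`.
#' @export
setClass("FrequencyResponse", representation(
  freqs = "numeric",
  H = "complex",
  magnitude = "numeric"
))

setValidity("FrequencyResponse", function(object) {
  if (length(object@freqs) != length(object@H)) return("freqs/H: length mismatch")
  if (length(object@magnitude) != length(object@H)) return("magnitude: length mismatch")
  if (is.unsorted(object@freqs, strictly = TRUE)) return("freqs: must be strictly ascending")
  if (max(abs(object@magnitude - Mod(object@H))) > 1e-12)
    return("magnitude: must equal abs(H)")
  TRUE
})

#' Relative power spectrum
#'
#' Periodogram of a single series normalized to sum to one.
#'
#' @slot freqs frequency grid in Hz.
#' @slot relativePower non-negative, sums to 1.
#' @export
setClass("PowerSpectrum", representation(
  freqs = "numeric",
  relativePower = "numeric"
))

setValidity("PowerSpectrum", function(object) {
  if (length(object@freqs) != length(object@relativePower))
    return("freqs/relativePower: length mismatch")
  if (any(object@relativePower < 0)) return("relativePower: must be non-negative")
  if (abs(sum(object@relativePower) - 1) > 1e-9)
    return("relativePower: must sum to 1")
  TRUE
})

#' Filter specification for the preprocessing recipes
#'
#' @slot kind one of `"bandpass-iir"`, `"highpass"`, `"lowpass"`.
#' @slot order filter order (Butterworth order for IIR; FIR length is chosen
#'   by the windowed-sinc design rule when 0).
#' @slot band one (high/low-pass) or two (bandpass) cutoff frequencies in Hz.
#' @slot passes number of repeated applications.
#' @slot zeroPhase apply forward-backward (zero phase) instead of causal.
#' @export
setClass("FilterSpec", representation(
  kind = "character",
  order = "integer",
  band = "numeric",
  passes = "integer",
  zeroPhase = "logical"
))

setValidity("FilterSpec", function(object) {
  if (!(object@kind %in% c("bandpass-iir", "highpass", "lowpass")))
    return("kind: must be bandpass-iir, highpass or lowpass")
  if (object@order < 0L) return("order: must be >= 0")
  nb <- length(object@band)
  if (object@kind == "bandpass-iir" && nb != 2L)
    return("band: bandpass needs two cutoffs")
  if (object@kind != "bandpass-iir" && nb != 1L)
    return("band: highpass/lowpass need one cutoff")
  if (any(object@band <= 0) || is.unsorted(object@band, strictly = TRUE) && nb == 2L)
    return("band: cutoffs must be positive and ascending")
  if (object@passes < 1L) return("passes: must be >= 1")
  TRUE
})

#' Cross-validation result
#'
#' @slot grid data.frame with columns `k` and `epsilon`, one row per
#'   hyperparameter pair evaluated.
#' @slot meanScores mean held-out score per pair.
#' @slot foldScores matrix `[n_pairs, n_folds]` of per-fold scores.
#' @slot chosenK,chosenEpsilon the selected pair (argmax of mean score; ties
#'   broken by smaller `k`, then larger `epsilon`).
#' @slot metricName `"accuracy"` or `"balanced_accuracy"`.
#' @export
setClass("CVResult", representation(
  grid = "data.frame",
  meanScores = "numeric",
  foldScores = "matrix",
  chosenK = "integer",
  chosenEpsilon = "numeric",
  metricName = "character"
))

setValidity("CVResult", function(object) {
  if (nrow(object@grid) != length(object@meanScores))
    return("meanScores: one per grid row required")
  if (nrow(object@foldScores) != nrow(object@grid))
    return("foldScores: one row per grid row required")
  TRUE
})

## ---- show methods ----

setMethod("show", "EEGEpochs", function(object) {
  d <- dim(object@data)
  tab <- table(object@labels)
  cat(sprintf("EEGEpochs: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], object@fs))
  cat("  labels: ", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "ContinuousEEG", function(object) {
  cat(sprintf("ContinuousEEG: %d channels x %d samples @ %g Hz\n",
              nrow(object@data), ncol(object@data), object@fs))
})

setMethod("show", "AugmentedEpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf("AugmentedEpochs: %d trials x %d rows (C=%d, k=%d) x %d samples\n",
              d[1L], d[2L], object@nChannels, object@k, d[3L]))
})

setMethod("show", "SpatialSpectralModel", function(object) {
  cat(sprintf("SpatialSpectralModel: %d filters (m=%d pairs) on D=%d (C=%d, k=%d), epsilon=%g\n",
              ncol(object@W), object@m, nrow(object@W), object@nChannels,
              object@k, object@epsilon))
  cat("  eigenvalues:", paste(sprintf("%.4f", object@eigvals), collapse = " "), "\n")
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult (%s): chosen k=%d, epsilon=%g over %d pairs x %d folds\n",
              object@metricName, object@chosenK, object@chosenEpsilon,
              nrow(object@grid), ncol(object@foldScores)))
})
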