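#' Construct an EEGEpochs object
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]`.
#' @param labels per-trial labels, coercible to integer, at most two distinct
#'   values (e.g. 1/2 or 0/1; the smaller value becomes condition 1 at fit time).
#' @param fs sampling rate in Hz.
#' @param channelNames optional channel names; defaults to `ch1, ch2, ...`.
#' @return A validated [EEGEpochs-class] object.
#' @examples
#' e <- eegEpochs(array(rnorm(2 * 3 * 10), c(2, 3, 10)), c(1, 2), fs = 100)
#' nTrials(e)
#' @export
eegEpochs <- function(data, labels, fs, channelNames = NULL) {
  data <- unname(as.array(data))
  if (length(dim(data)) != 3L)
    stopData("data: must be a 3-D array [trials x channels x samples]")
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(data)[2L]))
  labi <- suppressWarnings(as.integer(labels))
  if (anyNA(labi)) stopData("labels: must be coercible to integer")
  obj <- new("EEGEpochs", data = data, labels = labi, fs = as.numeric(fs),
             channelNames = as.character(channelNames))
  msg <- validObject(obj, test = TRUE)
  if (!isTRUE(msg)) stopData(msg)
  obj
}

#' Construct a ContinuousEEG object
#'
#' @param data numeric matrix `[n_channels, n_samples]`.
#' @param fs sampling rate in Hz.
#' @param channelNames optional channel names.
#' @return A validated [ContinuousEEG-class] object.
#' @export
continuousEEG <- function(data, fs, channelNames = NULL) {
  data <- unname(as.matrix(data))
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nrow(data)))
  obj <- new("ContinuousEEG", data = data, fs = as.numeric(fs),
             channelNames = as.character(channelNames))
  msg <- validObject(obj, test = TRUE)
  if (!isTRUE(msg)) stopData(msg)
  obj
}

#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("firHalfOrder", function(x) standardGeneric("firHalfOrder"))
#' @rdname accessors
#' @export
setGeneric("filterWeights", function(x) standardGeneric("filterWeights"))
#' @rdname accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' Accessors for the core classes
#'
#' `epochData` returns the raw tensor/matrix; `trialLabels` the per-trial
#' labels; `samplingRate` the rate in Hz; `nTrials`/`nChannels`/`nSamples`
#' the tensor dimensions; `firHalfOrder` the embedding half-order `k`;
#' `filterWeights` the `D x 2m` filter matrix of a fitted model;
#' `eigenValues` its aligned eigenvalues.
#'
#' @param x an object of one of the package's classes.
#' @name accessors
NULL

setMethod("epochData", "EEGEpochs", function(x) x@data)
setMethod("epochData", "ContinuousEEG", function(x) x@data)
setMethod("epochData", "AugmentedEpochs", function(x) x@data)
setMethod("trialLabels", "EEGEpochs", function(x) x@labels)
setMethod("trialLabels", "AugmentedEpochs", function(x) x@labels)
setMethod("samplingRate", "EEGEpochs", function(x) x@fs)
setMethod("samplingRate", "ContinuousEEG", function(x) x@fs)
setMethod("samplingRate", "AugmentedEpochs", function(x) x@fs)
setMethod("samplingRate", "SpatialSpectralModel", function(x) x@fs)
setMethod("channelNames", "EEGEpochs", function(x) x@channelNames)
setMethod("channelNames", "ContinuousEEG", function(x) x@channelNames)
setMethod("channelNames", "AugmentedEpochs", function(x) x@channelNames)
setMethod("channelNames", "SpatialSpectralModel", function(x) x@channelNames)
setMethod("nTrials", "EEGEpochs", function(x) dim(x@data)[1L])
setMethod("nTrials", "AugmentedEpochs", function(x) dim(x@data)[1L])
setMethod("nChannels", "EEGEpochs", function(x) dim(x@data)[2L])
setMethod("nChannels", "ContinuousEEG", function(x) nrow(x@data))
setMethod("nChannels", "AugmentedEpochs", function(x) x@nChannels)
setMethod("nChannels", "SpatialSpectralModel", function(x) x@nChannels)
setMethod("nSamples", "EEGEpochs", function(x) dim(x@data)[3L])
setMethod("nSamples", "ContinuousEEG", function(x) ncol(x@data))
setMethod("nSamples", "AugmentedEpochs", function(x) dim(x@data)[3L])
setMethod("firHalfOrder", "AugmentedEpochs", function(x) x@k)
setMethod("firHalfOrder", "SpatialSpectralModel", function(x) x@k)
setMethod("filterWeights", "SpatialSpectralModel", function(x) x@W)
setMethod("eigenValues", "SpatialSpectralModel", function(x) x@eigvals)
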