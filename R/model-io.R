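## Model serialization: one JSON document holding the full numeric payload at
## double precision (17 significant digits round-trip exactly).

#' Write a fitted model to JSON
#'
#' @param model a [SpatialSpectralModel-class].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
writeModel <- function(model, path) {
  msg <- validObject(model, test = TRUE)
  if (!isTRUE(msg)) stopData(msg)
  doc <- list(
    format = "ccssp-model",
    version = "1",
    k = model@k,
    epsilon = model@epsilon,
    m = model@m,
    n_channels = model@nChannels,
    fs = model@fs,
    channel_names = model@channelNames,
    eigvals = model@eigvals,
    W = model@W
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path file written by [writeModel()].
#' @return A validated [SpatialSpectralModel-class].
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stopData("no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "ccssp-model")
    stopData("not a model file (missing format tag): ", path)
  new("SpatialSpectralModel",
      W = matrix(as.numeric(doc$W), nrow = doc$n_channels * (2L * doc$k + 1L)),
      eigvals = as.numeric(doc$eigvals),
      k = as.integer(doc$k), epsilon = as.numeric(doc$epsilon),
      m = as.integer(doc$m), nChannels = as.integer(doc$n_channels),
      channelNames = as.character(doc$channel_names), fs = as.numeric(doc$fs))
}
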