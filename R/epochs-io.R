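## Epoch container I/O.
##
## HDF5 schema (single file): datasets `data` (trials x channels x samples),
## `labels` (integer per trial), `channel_names` (strings), plus scalar
## attribute `fs` on the file root. The numeric payload round-trips bit-exactly.

#' Write epochs to the HDF5 container
#'
#' @param epochs a valid [EEGEpochs-class] object.
#' @param path destination file; overwritten if it exists.
#' @return Invisibly, `path`.
#' @seealso [readEpochs()]
#' @export
writeEpochs <- function(epochs, path) {
  if (!is(epochs, "EEGEpochs")) stopData("epochs: not an EEGEpochs object")
  msg <- validObject(epochs, test = TRUE)
  if (!isTRUE(msg)) stopData(msg)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stopData("path not writable: ", path)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  suppressMessages(rhdf5::h5write(epochs@data, path, "data"))
  rhdf5::h5write(epochs@labels, path, "labels")
  rhdf5::h5write(epochs@channelNames, path, "channel_names")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(as.numeric(epochs@fs), fid, "fs")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read epochs from the HDF5 container
#'
#' @param path file written by [writeEpochs()] or matching its schema.
#' @return A validated [EEGEpochs-class] object.
#' @export
readEpochs <- function(path) {
  if (!file.exists(path)) stopData("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  present <- rhdf5::h5ls(path)$name
  for (ds in c("data", "labels", "channel_names"))
    if (!(ds %in% present))
      stopData("container schema: missing dataset `", ds, "` in ", path)
  attrs <- rhdf5::h5readAttributes(path, "/")
  if (is.null(attrs$fs))
    stopData("container schema: missing root attribute `fs` in ", path)
  data <- rhdf5::h5read(path, "data")
  labels <- as.integer(rhdf5::h5read(path, "labels"))
  ch <- as.character(rhdf5::h5read(path, "channel_names"))
  if (length(dim(data)) != 3L)
    stopData("container schema: `data` must be 3-D in ", path)
  eegEpochs(data, labels, as.numeric(attrs$fs), ch)
}

#' Read epochs from a CSV fixture directory
#'
#' The CSV dialect mirrors the HDF5 schema for plain-text fixtures: one
#' header-free `trial_<i>.csv` per trial (channels as rows, comma-separated),
#' `labels.csv` (one label per line), and `meta.csv` with a `fs,<Hz>` line
#' followed by one `channel,<name>` line per channel.
#'
#' @param dir directory holding the fixture files.
#' @return A validated [EEGEpochs-class] object identical to its HDF5 twin.
#' @export
readEpochsCSV <- function(dir) {
  if (!dir.exists(dir)) stopData("no such directory: ", dir)
  metaPath <- file.path(dir, "meta.csv")
  labPath <- file.path(dir, "labels.csv")
  if (!file.exists(metaPath)) stopData("fixture schema: missing meta.csv in ", dir)
  if (!file.exists(labPath)) stopData("fixture schema: missing labels.csv in ", dir)
  meta <- utils::read.csv(metaPath, header = FALSE, stringsAsFactors = FALSE)
  fs <- as.numeric(meta[meta[[1L]] == "fs", 2L])
  ch <- as.character(meta[meta[[1L]] == "channel", 2L])
  if (length(fs) != 1L || is.na(fs)) stopData("fixture schema: meta.csv lacks fs")
  labels <- scan(labPath, what = integer(), quiet = TRUE)
  trials <- lapply(seq_along(labels), function(i) {
    p <- file.path(dir, sprintf("trial_%d.csv", i))
    if (!file.exists(p)) stopData("fixture schema: missing ", basename(p))
    as.matrix(utils::read.csv(p, header = FALSE))
  })
  dims <- vapply(trials, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stopData("fixture schema: trial matrices have inconsistent shapes")
  data <- array(0, c(length(trials), dims[1L, 1L], dims[2L, 1L]))
  for (i in seq_along(trials)) data[i, , ] <- trials[[i]]
  eegEpochs(data, labels, fs, ch)
}

#' Write epochs as a CSV fixture directory
#'
#' Inverse of [readEpochsCSV()]; used to materialize small plain-text twins
#' of HDF5 containers.
#'
#' @param epochs a valid [EEGEpochs-class] object.
#' @param dir destination directory, created if absent.
#' @return Invisibly, `dir`.
#' @export
writeEpochsCSV <- function(epochs, dir) {
  msg <- validObject(epochs, test = TRUE)
  if (!isTRUE(msg)) stopData(msg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(paste0("fs,", format(epochs@fs, digits = 17)),
               paste0("channel,", epochs@channelNames)),
             file.path(dir, "meta.csv"))
  writeLines(as.character(epochs@labels), file.path(dir, "labels.csv"))
  for (i in seq_len(nTrials(epochs))) {
    m <- epochs@data[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = nChannels(epochs))
    lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
    writeLines(lines, file.path(dir, sprintf("trial_%d.csv", i)))
  }
  invisible(dir)
}
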