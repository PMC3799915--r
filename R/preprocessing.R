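## Preprocessing: the two recipes used for motor-imagery (MI) and rapid serial
## visual presentation (RSVP) data, plus epoch segmentation.
##
## MI recipe: 8-30 Hz fifth-order Butterworth bandpass on epochs, causal by
## default. RSVP recipe: 1 Hz high-pass applied twice, then 25 Hz low-pass, on
## continuous data; emulated with linear-phase windowed-sinc FIR filters
## applied zero-phase (the 0-500 ms epoch window is latency-sensitive), then
## segmentation into 0-500 ms event-locked windows.

#' Construct a filter specification
#'
#' @param kind `"bandpass-iir"` (Butterworth), `"highpass"` or `"lowpass"`
#'   (linear-phase windowed-sinc FIR).
#' @param order filter order. For FIR kinds, `order = 0` selects the design
#'   rule `3 * fs / cutoff` rounded up to even at application time.
#' @param band one cutoff (high/low-pass) or two ascending cutoffs (bandpass),
#'   in Hz; must lie strictly inside `(0, fs/2)` when applied.
#' @param passes number of repeated applications (default 1).
#' @param zeroPhase forward-backward filtering (default `FALSE`: causal).
#' @return A validated [FilterSpec-class] object.
#' @export
filterSpec <- function(kind, order = 0L, band, passes = 1L, zeroPhase = FALSE) {
  obj <- new("FilterSpec", kind = kind, order = as.integer(order),
             band = as.numeric(band), passes = as.integer(passes),
             zeroPhase = isTRUE(zeroPhase))
  msg <- validObject(obj, test = TRUE)
  if (!isTRUE(msg)) stopUsage(msg)
  obj
}

## Windowed-sinc (Hamming) linear-phase FIR taps; `order` must be even.
designSincFIR <- function(kind, cutoff, fs, order) {
  if (order %% 2L != 0L) order <- order + 1L
  M <- order
  n <- 0:M
  x <- n - M / 2
  fc <- cutoff / fs
  h <- 2 * fc * ifelse(x == 0, 1, sin(2 * pi * fc * x) / (2 * pi * fc * x))
  w <- 0.54 - 0.46 * cos(2 * pi * n / M)
  h <- h * w
  h <- h / sum(h)                       # unit DC gain low-pass
  if (kind == "highpass") {
    h <- -h
    h[M / 2 + 1L] <- h[M / 2 + 1L] + 1  # spectral inversion
  }
  h
}

applyFilterVector <- function(x, spec, fs) {
  ny <- fs / 2
  if (any(spec@band >= ny))
    stopUsage("filter cutoff at or above Nyquist (", ny, " Hz): ",
              paste(spec@band, collapse = ", "))
  if (spec@kind == "bandpass-iir") {
    bt <- signal::butter(spec@order, spec@band / ny, type = "pass")
    b <- bt$b; a <- bt$a
  } else {
    ord <- spec@order
    if (ord == 0L) ord <- 2L * ceiling(3 * fs / spec@band / 2)
    b <- designSincFIR(spec@kind, spec@band, fs, ord)
    a <- 1
  }
  for (p in seq_len(spec@passes)) {
    x <- if (spec@zeroPhase) as.numeric(signal::filtfilt(b, a, x))
         else as.numeric(signal::filter(b, a, x))
  }
  x
}

#' Apply a filter channel-wise
#'
#' Filters every channel independently; for epoched input every trial and
#' channel. Shape is preserved; `passes = n` applies the filter `n` times in
#' sequence.
#'
#' @param x a [ContinuousEEG-class] or [EEGEpochs-class] object.
#' @param spec a [FilterSpec-class].
#' @return An object of the same class as `x`.
#' @export
setGeneric("applyFilter", function(x, spec) standardGeneric("applyFilter"))

#' @rdname applyFilter
#' @export
setMethod("applyFilter", "ContinuousEEG", function(x, spec) {
  d <- x@data
  for (c in seq_len(nrow(d))) d[c, ] <- applyFilterVector(d[c, ], spec, x@fs)
  continuousEEG(d, x@fs, x@channelNames)
})

#' @rdname applyFilter
#' @export
setMethod("applyFilter", "EEGEpochs", function(x, spec) {
  d <- x@data
  for (i in seq_len(dim(d)[1L]))
    for (c in seq_len(dim(d)[2L]))
      d[i, c, ] <- applyFilterVector(d[i, c, ], spec, x@fs)
  eegEpochs(d, x@labels, x@fs, x@channelNames)
})

#' Segment a continuous recording into event-locked epochs
#'
#' Each epoch is the half-open window `[t0, t1)` seconds relative to its
#' onset: `n_samples = round((t1 - t0) * fs)` samples starting at
#' `onset + round(t0 * fs)`; the sample at exactly `t1` is excluded.
#'
#' @param cont a [ContinuousEEG-class] recording.
#' @param onsets event onset sample indices (1-based).
#' @param window numeric `c(t0, t1)` in seconds relative to each onset.
#' @param labels per-onset condition labels.
#' @return An [EEGEpochs-class] object with `length(onsets)` trials.
#' @export
segmentEpochs <- function(cont, onsets, window, labels) {
  if (length(onsets) != length(labels))
    stopUsage("onsets and labels must have equal length")
  fs <- cont@fs
  n <- round((window[2L] - window[1L]) * fs)
  if (n < 1L) stopUsage("window [", window[1L], ", ", window[2L], ") is empty")
  off <- round(window[1L] * fs)
  C <- nrow(cont@data); Tn <- ncol(cont@data)
  starts <- as.integer(onsets) + off
  bad <- which(starts < 1L | starts + n - 1L > Tn)
  if (length(bad))
    stopData("window exceeds the recording for onsets: ",
             paste(onsets[bad], collapse = ", "))
  data <- array(0, c(length(onsets), C, n))
  for (i in seq_along(onsets))
    data[i, , ] <- cont@data[, starts[i] + 0:(n - 1L), drop = FALSE]
  eegEpochs(data, if (length(labels)) labels else integer(0), fs,
            cont@channelNames)
}

#' Named preprocessing presets
#'
#' `"mi"`: 8-30 Hz order-5 Butterworth bandpass applied to epochs (cue-locked
#' window 0.5-2.5 s). `"rsvp"`: 1 Hz high-pass applied twice then 25 Hz
#' low-pass, both zero-phase FIR on continuous data, followed by segmentation
#' into 0-500 ms event-locked windows.
#'
#' @param name `"mi"` or `"rsvp"`.
#' @return A list with elements `filters` (list of [FilterSpec-class]),
#'   `domain` (`"epochs"` or `"continuous"`) and `window` (seconds).
#' @export
preprocessPreset <- function(name) {
  switch(name,
    mi = list(
      filters = list(filterSpec("bandpass-iir", order = 5L, band = c(8, 30))),
      domain = "epochs",
      window = c(0.5, 2.5)),
    rsvp = list(
      filters = list(
        filterSpec("highpass", band = 1, passes = 2L, zeroPhase = TRUE),
        filterSpec("lowpass", band = 25, zeroPhase = TRUE)),
      domain = "continuous",
      window = c(0, 0.5)),
    stopUsage("unknown preprocessing preset: ", name))
}
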