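#' @include AllClasses.R
NULL

#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @export
setGeneric("paradigmOf", function(x) standardGeneric("paradigmOf"))
#' @export
setGeneric("epochArray", function(x) standardGeneric("epochArray"))
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @export
setGeneric("bandOf", function(x) standardGeneric("bandOf"))
#' @export
setGeneric("pliBand", function(x, band) standardGeneric("pliBand"))

#' @describeIn Recording-class sampling rate in samples/s
#' @param x object
#' @export
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @describeIn Recording-class channel labels in storage order
#' @export
setMethod("channelLabels", "Recording", function(x) x@channelLabels)
#' @describeIn Recording-class the channels x samples signal matrix
#' @export
setMethod("signalData", "Recording", function(x) x@data)
#' @describeIn Recording-class subject identifier
#' @export
setMethod("subjectId", "Recording", function(x) x@subjectId)
#' @describeIn Recording-class recording paradigm label
#' @export
setMethod("paradigmOf", "Recording", function(x) x@paradigm)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s' [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, object@paradigm, nrow(object@data),
              ncol(object@data), object@fs, ncol(object@data) / object@fs))
})

#' @describeIn EpochSet-class sampling rate
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @describeIn EpochSet-class channel labels
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)
#' @describeIn EpochSet-class the n_epochs x channels x samples array
#' @export
setMethod("epochArray", "EpochSet", function(x) x@epochs)
#' @describeIn EpochSet-class number of epochs
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@epochs)[1])
#' @describeIn EpochSet-class band the epochs are filtered to (NULL if broadband)
#' @export
setMethod("bandOf", "EpochSet", function(x) x@band)

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  bn <- if (is.null(object@band)) "broadband" else object@band@name
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples @ %g Hz [%s]\n",
              d[1], d[2], d[3], object@fs, bn))
})

#' @describeIn AnalyticSignal-class sampling rate
#' @export
setMethod("samplingRate", "AnalyticSignal", function(x) x@fs)
#' @describeIn AnalyticSignal-class channel labels
#' @export
setMethod("channelLabels", "AnalyticSignal", function(x) x@channelLabels)
#' @describeIn AnalyticSignal-class band of the underlying epochs
#' @export
setMethod("bandOf", "AnalyticSignal", function(x) x@band)
#' @describeIn AnalyticSignal-class number of epochs
#' @export
setMethod("nEpochs", "AnalyticSignal", function(x) dim(x@phase)[1])

#' Instantaneous phase array of an analytic signal
#' @param x an [AnalyticSignal-class]
#' @return n_epochs x channels x samples array of phases in (-pi, pi]
#' @export
phaseArray <- function(x) x@phase

#' Hilbert envelope array of an analytic signal
#' @param x an [AnalyticSignal-class]
#' @return n_epochs x channels x samples array of envelopes
#' @export
amplitudeArray <- function(x) x@amplitude

setMethod("show", "AnalyticSignal", function(object) {
  d <- dim(object@phase)
  cat(sprintf("AnalyticSignal [%s]: %d epochs x %d channels x %d samples\n",
              object@band@name, d[1], d[2], d[3]))
})

#' @describeIn ConnectivityTensor-class channel labels indexing the matrices
#' @export
setMethod("channelLabels", "ConnectivityTensor", function(x) x@channelLabels)
#' @describeIn ConnectivityTensor-class number of epochs used in the estimate
#' @export
setMethod("nEpochs", "ConnectivityTensor", function(x) x@nEpochs)
#' @describeIn ConnectivityTensor-class extract one band's PLI matrix
#' @param band band name
#' @export
setMethod("pliBand", "ConnectivityTensor", function(x, band) {
  if (!band %in% names(x@pli))
    stop(sprintf("band '%s' not present (have: %s)", band,
                 paste(names(x@pli), collapse = ", ")))
  x@pli[[band]]
})

setMethod("show", "ConnectivityTensor", function(object) {
  cat(sprintf("ConnectivityTensor: %d channels, bands {%s}, %d epochs\n",
              length(object@channelLabels),
              paste(names(object@pli), collapse = ", "), object@nEpochs))
})

setMethod("show", "ClassifierSpec", function(object) {
  ps <- if (length(object@params))
    paste(names(object@params), unlist(object@params),
          sep = "=", collapse = ", ") else "library defaults"
  cat(sprintf("ClassifierSpec '%s' (%s)\n", object@name, ps))
})
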