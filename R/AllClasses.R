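#' @include eegparadigm-package.R
NULL

#' Canonical 19-electrode 10-20 montage
#'
#' The 19 scalp electrodes retained for analysis, in canonical order. All
#' recordings are restricted and reordered to this montage on load, so every
#' connectivity matrix and feature block shares one channel ordering.
#'
#' @return Character vector of 19 upper-case electrode labels.
#' @export
#' @examples
#' montage19()
montage19 <- function() {
  c("FP1", "FP2", "F3", "F4", "F7", "F8", "FZ", "T7", "T8", "P7", "P8",
    "C3", "C4", "CZ", "P3", "P4", "PZ", "O1", "O2")
}

#' Scalp region assignment for the 19-electrode montage
#'
#' Groups electrodes into frontal (F), parietal/central (P), occipital (O)
#' and temporal (T) regions, the grouping used when reporting per-electrode
#' feature significance.
#'
#' @return Named character vector mapping electrode label to region code.
#' @export
electrodeRegions <- function() {
  reg <- c(
    FP1 = "F", FP2 = "F", F3 = "F", F4 = "F", F7 = "F", F8 = "F", FZ = "F",
    C3 = "P", C4 = "P", CZ = "P", P3 = "P", P4 = "P", P7 = "P", P8 = "P",
    PZ = "P", O1 = "O", O2 = "O", T7 = "T", T8 = "T")
  reg[montage19()]
}

#' Frequency band definition
#'
#' @slot name band name, one of "delta", "theta", "alpha", "beta", "gamma"
#'   (free names are allowed for custom bands)
#' @slot low lower band edge in Hz
#' @slot high upper band edge in Hz
#' @export
setClass("BandDefinition",
  representation(name = "character", low = "numeric", high = "numeric"))

setValidity("BandDefinition", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("band name must be a single non-empty string")
  if (length(object@low) != 1L || length(object@high) != 1L)
    return("band edges must be scalars")
  if (!is.finite(object@low) || !is.finite(object@high))
    return("band edges must be finite")
  if (object@low <= 0) return("lower band edge must be > 0 Hz")
  if (object@low >= object@high) return("band requires low < high")
  TRUE
})

#' @rdname BandDefinition-class
#' @param name band name
#' @param low,high band edges in Hz
#' @export
bandDefinition <- function(name, low, high) {
  new("BandDefinition", name = as.character(name),
      low = as.numeric(low), high = as.numeric(high))
}

#' Canonical EEG frequency band table
#'
#' delta 1-4 Hz, theta 4-8 Hz, alpha 8-12 Hz, beta 12-30 Hz and gamma
#' 30-49 Hz. The gamma band is bounded above at 49 Hz because the broadband
#' front-end filter removes everything above 49 Hz.
#'
#' @return Named list of [BandDefinition-class] objects.
#' @export
#' @examples
#' canonicalBands()[["alpha"]]
canonicalBands <- function() {
  list(
    delta = bandDefinition("delta", 1, 4),
    theta = bandDefinition("theta", 4, 8),
    alpha = bandDefinition("alpha", 8, 12),
    beta  = bandDefinition("beta", 12, 30),
    gamma = bandDefinition("gamma", 30, 49))
}

setClassUnion("BandDefinitionOrNULL", c("BandDefinition", "NULL"))

.PARADIGMS <- c("eyes_closed", "eyes_open", "free_viewing")

#' Multichannel EEG recording
#'
#' One subject's continuous signal for one recording paradigm. Rows are
#' channels (canonical montage order after [readRecording()]), columns are
#' samples in microvolts.
#'
#' @slot data channels x samples numeric matrix (microvolts)
#' @slot fs sampling rate in samples/s
#' @slot channelLabels ordered channel labels, one per row of `data`
#' @slot subjectId subject identifier
#' @slot paradigm one of "eyes_closed", "eyes_open", "free_viewing"
#' @export
setClass("Recording",
  representation(data = "matrix", fs = "numeric", channelLabels = "character",
                 subjectId = "character", paradigm = "character"))

setValidity("Recording", function(object) {
  if (!is.numeric(object@data)) return("data must be numeric")
  if (nrow(object@data) != length(object@channelLabels))
    return("channelLabels length must equal the channel (row) dimension")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive number")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    return("signal contains non-finite samples")
  if (length(object@paradigm) != 1L ||
      !(object@paradigm %in% c(.PARADIGMS, NA_character_)))
    return(sprintf("paradigm must be one of %s",
                   paste(.PARADIGMS, collapse = ", ")))
  TRUE
})

#' @rdname Recording-class
#' @param data channels x samples numeric matrix
#' @param fs sampling rate (samples/s)
#' @param channelLabels character vector of channel labels
#' @param subjectId subject identifier
#' @param paradigm recording paradigm label
#' @export
recording <- function(data, fs, channelLabels = rownames(data),
                      subjectId = "S01", paradigm = "eyes_closed") {
  if (is.null(channelLabels))
    channelLabels <- sprintf("CH%02d", seq_len(nrow(data)))
  new("Recording", data = unname(as.matrix(data)), fs = as.numeric(fs),
      channelLabels = toupper(as.character(channelLabels)),
      subjectId = as.character(subjectId), paradigm = as.character(paradigm))
}

#' Stack of fixed-length epochs
#'
#' Non-overlapping contiguous segments cut from a continuous recording,
#' optionally band-filtered (then `band` records the band).
#'
#' @slot epochs numeric array n_epochs x channels x samples_per_epoch
#' @slot fs sampling rate
#' @slot channelLabels channel labels
#' @slot band [BandDefinition-class] or NULL for broadband epochs
#' @export
setClass("EpochSet",
  representation(epochs = "array", fs = "numeric",
                 channelLabels = "character", band = "BandDefinitionOrNULL"))

setValidity("EpochSet", function(object) {
  d <- dim(object@epochs)
  if (length(d) != 3L) return("epochs must be a 3-d array")
  if (d[2] != length(object@channelLabels))
    return("channel dimension must match channelLabels")
  if (length(object@fs) != 1L || object@fs <= 0) return("fs must be positive")
  TRUE
})

#' Per-epoch analytic signal (Hilbert phase and envelope)
#'
#' @slot phase instantaneous phase in radians, in (-pi, pi], same layout as
#'   the epochs it was derived from
#' @slot amplitude Hilbert envelope (microvolts), non-negative
#' @slot fs sampling rate
#' @slot channelLabels channel labels
#' @slot band the band the epochs were filtered to
#' @export
setClass("AnalyticSignal",
  representation(phase = "array", amplitude = "array", fs = "numeric",
                 channelLabels = "character", band = "BandDefinition"))

setValidity("AnalyticSignal", function(object) {
  if (!identical(dim(object@phase), dim(object@amplitude)))
    return("phase and amplitude must share dimensions")
  if (any(object@amplitude < 0)) return("amplitude must be non-negative")
  TRUE
})

#' Per-band phase lag index connectivity
#'
#' Symmetric zero-diagonal channel x channel PLI matrices, one per band,
#' for a single subject/paradigm.
#'
#' @slot pli named list (band name -> channels x channels matrix in [0,1])
#' @slot nEpochs number of epochs the estimate used
#' @slot channelLabels channel labels indexing the matrices
#' @export
setClass("ConnectivityTensor",
  representation(pli = "list", nEpochs = "integer",
                 channelLabels = "character"))

setValidity("ConnectivityTensor", function(object) {
  for (bn in names(object@pli)) {
    m <- object@pli[[bn]]
    nc <- length(object@channelLabels)
    if (!is.matrix(m) || nrow(m) != nc || ncol(m) != nc)
      return(sprintf("band %s: matrix must be %d x %d", bn, nc, nc))
    if (max(abs(m - t(m))) > 1e-12)
      return(sprintf("band %s: PLI matrix must be symmetric", bn))
    if (any(abs(diag(m)) > 1e-12))
      return(sprintf("band %s: PLI diagonal must be zero", bn))
    if (min(m) < -1e-12 || max(m) > 1 + 1e-12)
      return(sprintf("band %s: PLI entries must lie in [0,1]", bn))
  }
  TRUE
})

#' Subjects-by-features container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' 12-family x 19-channel feature block. Rows are features (rowData carries
#' `family` and `channel`), columns are subjects (colData carries `subject_id`,
#' `group`, `paradigm` and the four cognitive scores).
#'
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment")

.FEATURE_FAMILIES <- c("psd_delta", "psd_theta", "psd_alpha", "psd_beta",
                       "psd_gamma", "de_delta", "de_theta", "de_alpha",
                       "de_beta", "de_gamma", "aac", "dpac")

setValidity("FeatureMatrix", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("family", "channel") %in% colnames(rd)))
    return("rowData must carry 'family' and 'channel'")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("subject_id", "group", "paradigm") %in% colnames(cd)))
    return("colData must carry 'subject_id', 'group', 'paradigm'")
  TRUE
})

#' Classifier configuration for the benchmark
#'
#' Fixed hyperparameters: AdaBoost.M1 on decision-tree base learners with
#' 100 learners; KNN with k = 5; Gaussian naive Bayes; random forest with
#' 100 trees; linear SVM with C = 0.25; CART decision tree. Hyperparameters
#' are part of the specification and are not tuned.
#'
#' @slot name classifier identifier
#' @slot params named list of fixed hyperparameters
#' @export
setClass("ClassifierSpec",
  representation(name = "character", params = "list"))

.CLASSIFIERS <- c("ensemble_adaboost", "knn", "naive_bayes", "random_forest",
                  "svm_linear", "decision_tree")

setValidity("ClassifierSpec", function(object) {
  if (!(object@name %in% .CLASSIFIERS))
    return(sprintf("unknown classifier '%s'; expected one of %s",
                   object@name, paste(.CLASSIFIERS, collapse = ", ")))
  TRUE
})

#' @rdname ClassifierSpec-class
#' @param name one of `"ensemble_adaboost"`, `"knn"`, `"naive_bayes"`,
#'   `"random_forest"`, `"svm_linear"`, `"decision_tree"`
#' @export
classifierSpec <- function(name) {
  params <- switch(name,
    ensemble_adaboost = list(n_learners = 100L),
    knn = list(k = 5L),
    naive_bayes = list(),
    random_forest = list(n_trees = 100L),
    svm_linear = list(cost = 0.25),
    decision_tree = list(),
    list())
  new("ClassifierSpec", name = name, params = params)
}

#' All six benchmark classifiers
#' @return list of [ClassifierSpec-class]
#' @export
allClassifierSpecs <- function() {
  stats::setNames(lapply(.CLASSIFIERS, classifierSpec), .CLASSIFIERS)
}
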