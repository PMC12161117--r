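#' @include AllClasses.R dsp.R
NULL

#' Average re-reference
#'
#' Subtracts the instantaneous mean across channels from every channel, the
#' average-reference montage. After re-referencing the mean over channels is
#' zero at every sample; applying it twice is a no-op.
#'
#' @param rec a [Recording-class]
#' @return the re-referenced [Recording-class]
#' @export
rereferenceAverage <- function(rec) {
  stopifnot(is(rec, "Recording"))
  if (nrow(rec@data) < 2)
    stop("average re-reference requires at least 2 channels")
  rec@data <- sweep(rec@data, 2, colMeans(rec@data))
  rec
}

#' Broadband front-end filter
#'
#' 1-49 Hz zero-phase Butterworth bandpass followed by a 50 Hz notch,
#' removing drift, high-frequency noise and power-line contamination.
#' All filters run forward-backward so the output has zero phase shift.
#'
#' @param rec a [Recording-class]
#' @param low,high bandpass edges in Hz (default 1 and 49)
#' @param notch_hz power-line notch frequency (default 50); `NA` disables
#' @param order Butterworth order applied in each direction (default 4)
#' @param notch_q notch quality factor (default 30)
#' @return filtered [Recording-class]
#' @export
filterBroadband <- function(rec, low = 1, high = 49, notch_hz = 50,
                            order = 4L, notch_q = 30) {
  stopifnot(is(rec, "Recording"))
  if (rec@fs < 2 * high)
    stop(sprintf("sampling rate %g Hz too low for a %g Hz band edge",
                 rec@fs, high))
  bp <- .butter_bandpass(low, high, rec@fs, order)
  # the high-Q notch rings for ~Q cycles, so continuous recordings get a
  # longer reflection pad than the per-epoch band filters
  npad <- min(round(3 * rec@fs), ncol(rec@data) - 1L)
  rec@data <- .filtfilt_rows(bp$b, bp$a, rec@data, npad)
  if (!is.na(notch_hz)) {
    nf <- .notch_biquad(notch_hz, rec@fs, notch_q)
    rec@data <- .filtfilt_rows(nf$b, nf$a, rec@data, npad)
  }
  rec
}

#' Segment a recording into non-overlapping epochs
#'
#' Cuts the continuous signal into contiguous non-overlapping epochs of
#' `epoch_s` seconds; a trailing remainder shorter than one epoch is
#' discarded. Epoch k covers the half-open interval [k*epoch_s, (k+1)*epoch_s).
#'
#' @param rec a [Recording-class]
#' @param epoch_s epoch length in seconds (default 6)
#' @return an [EpochSet-class] with `floor(duration/epoch_s)` epochs
#' @export
segmentEpochs <- function(rec, epoch_s = 6) {
  stopifnot(is(rec, "Recording"))
  spe <- round(epoch_s * rec@fs)
  nsamp <- ncol(rec@data)
  nep <- floor(nsamp / spe)
  if (nep < 1)
    stop(sprintf("recording of %.2f s is shorter than one %g-s epoch",
                 nsamp / rec@fs, epoch_s))
  nch <- nrow(rec@data)
  ep <- aperm(array(rec@data[, seq_len(nep * spe), drop = FALSE],
                    c(nch, spe, nep)), c(3, 1, 2))
  new("EpochSet", epochs = ep, fs = rec@fs,
      channelLabels = rec@channelLabels, band = NULL)
}

#' Concatenate an epoch stack back into a continuous matrix
#'
#' Inverse of [segmentEpochs()] up to the discarded remainder.
#'
#' @param es an [EpochSet-class]
#' @return channels x samples matrix
#' @export
concatenateEpochs <- function(es) {
  d <- dim(es@epochs)
  out <- matrix(NA_real_, d[2], d[1] * d[3])
  for (k in seq_len(d[1]))
    out[, ((k - 1L) * d[3] + 1L):(k * d[3])] <- matrix(es@epochs[k, , ],
                                                       d[2], d[3])
  out
}

#' Band-decompose epochs with a zero-phase Butterworth filter
#'
#' Filters every epoch to one frequency band. Each epoch is padded with one
#' second of odd-reflected signal per side before the forward-backward pass
#' so that slow-band (delta) transients do not contaminate 6-s epochs.
#'
#' @param es a broadband [EpochSet-class] (band not yet set)
#' @param band a [BandDefinition-class], e.g. an entry of [canonicalBands()]
#' @param order Butterworth order per direction (default 4)
#' @return band-filtered [EpochSet-class] with `band` recorded
#' @export
bandFilter <- function(es, band, order = 4L) {
  stopifnot(is(es, "EpochSet"), is(band, "BandDefinition"))
  if (!is.null(es@band))
    stop(sprintf("epochs already filtered to band '%s'", es@band@name))
  bp <- .butter_bandpass(band@low, band@high, es@fs, order)
  d <- dim(es@epochs)
  npad <- min(round(es@fs), d[3] - 1L)
  # filter all (epoch, channel) series in one pass: samples x series
  m <- matrix(aperm(es@epochs, c(3, 1, 2)), d[3], d[1] * d[2])
  m <- .filtfilt_mat(bp$b, bp$a, .filter_zi(bp$b, bp$a), m,
                     as.integer(npad))
  out <- aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
  new("EpochSet", epochs = out, fs = es@fs,
      channelLabels = es@channelLabels, band = band)
}
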