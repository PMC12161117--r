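#' @include AllClasses.R dsp.R preprocess.R
NULL

#' Hilbert analytic signal of band-filtered epochs
#'
#' Computes the analytic signal of every epoch and channel by the
#' frequency-domain Hilbert construction; the instantaneous phase is the
#' complex argument and the envelope the modulus. Only band-filtered epochs
#' are accepted — phase is not meaningful for broadband signals.
#'
#' @param es a band-filtered [EpochSet-class]
#' @return an [AnalyticSignal-class]
#' @export
analyticSignal <- function(es) {
  stopifnot(is(es, "EpochSet"))
  if (is.null(es@band))
    stop("analytic signal requires band-filtered epochs; apply bandFilter() first")
  d <- dim(es@epochs)
  # one batched FFT over all (epoch, channel) series
  z <- .analytic_cols(matrix(aperm(es@epochs, c(3, 1, 2)), d[3], d[1] * d[2]))
  ph <- aperm(array(Arg(z), c(d[3], d[1], d[2])), c(2, 3, 1))
  am <- aperm(array(Mod(z), c(d[3], d[1], d[2])), c(2, 3, 1))
  new("AnalyticSignal", phase = ph, amplitude = am, fs = es@fs,
      channelLabels = es@channelLabels, band = es@band)
}

#' Phase lag index matrix
#'
#' For each channel pair, the phase difference is wrapped to (-pi, pi] at
#' every sample; its sign (-1, 0, +1, with sgn(0) = 0) is averaged over the
#' samples of each epoch, those per-epoch means are averaged across epochs,
#' and the PLI is the absolute value of that grand mean. PLI is 0 for
#' consistently zero-lag (or random-lag) phase relations and 1 for a
#' consistent nonzero lag; the diagonal is set to 0.
#'
#' @param phases an [AnalyticSignal-class]
#' @return symmetric channels x channels matrix with entries in [0, 1]
#' @export
pliMatrix <- function(phases) {
  stopifnot(is(phases, "AnalyticSignal"))
  d <- dim(phases@phase)
  nch <- d[2]
  if (nch < 2) stop("PLI requires at least two channels")
  # epochs share one length, so the epoch-then-grand average equals the mean
  # over all concatenated samples
  P <- matrix(aperm(phases@phase, c(2, 3, 1)), nch, d[1] * d[3])
  out <- .pli_pairs(P)
  dimnames(out) <- list(phases@channelLabels, phases@channelLabels)
  out
}

# Phase-only PLI for one band-filtered EpochSet: algebraically identical to
# pliMatrix(analyticSignal(es)) but skips the envelope computation and one
# array permutation; the equivalence is pinned by a test.
.pli_from_epochs <- function(es) {
  d <- dim(es@epochs)
  m <- matrix(aperm(es@epochs, c(3, 1, 2)), d[3], d[1] * d[2])
  A <- Arg(.analytic_cols(m))
  P <- matrix(aperm(array(A, c(d[3], d[1], d[2])), c(3, 1, 2)),
              d[2], d[1] * d[3])
  out <- .pli_pairs(P)
  dimnames(out) <- list(es@channelLabels, es@channelLabels)
  out
}

#' Per-band PLI connectivity for one subject
#'
#' Band-filters broadband epochs to each requested band, extracts Hilbert
#' phases and assembles the per-band PLI matrices.
#'
#' @param es broadband [EpochSet-class]
#' @param bands named list of [BandDefinition-class] (default all five
#'   canonical bands)
#' @return a [ConnectivityTensor-class]
#' @export
connectivityTensor <- function(es, bands = canonicalBands()) {
  stopifnot(is(es, "EpochSet"))
  if (!is.null(es@band)) stop("connectivityTensor expects broadband epochs")
  pli <- lapply(bands, function(bd) .pli_from_epochs(bandFilter(es, bd)))
  names(pli) <- vapply(bands, function(bd) bd@name, character(1))
  new("ConnectivityTensor", pli = pli, nEpochs = dim(es@epochs)[1],
      channelLabels = es@channelLabels)
}

# Mean Welch density per channel across epochs: channels x frequency matrix.
.welch_epochs <- function(es, seg_s = 2, overlap = 0.5) {
  d <- dim(es@epochs)
  acc <- NULL
  for (k in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      w <- .welch_psd(es@epochs[k, ch, ], es@fs, seg_s, overlap)
      if (is.null(acc)) {
        acc <- matrix(0, d[2], length(w$density))
        freq <- w$freq; df <- w$df
      }
      acc[ch, ] <- acc[ch, ] + w$density
    }
  }
  list(density = acc / d[1], freq = freq, df = df)
}

#' Band power from the Welch periodogram
#'
#' Welch power spectral density (2-s Hamming segments, 50% overlap,
#' one-sided density) per epoch and channel, integrated over the half-open
#' band [low, high) Hz and averaged across epochs.
#'
#' @param es broadband [EpochSet-class]
#' @param band a [BandDefinition-class]
#' @param seg_s,overlap Welch segment length (s) and fractional overlap
#' @return named per-channel power vector (microvolt^2)
#' @export
psdBandPower <- function(es, band, seg_s = 2, overlap = 0.5) {
  stopifnot(is(es, "EpochSet"), is(band, "BandDefinition"))
  if (!is.null(es@band))
    stop("psdBandPower expects broadband epochs (PSD is band-resolved itself)")
  if (band@high > es@fs / 2)
    stop("band extends beyond the spectral range of the recording")
  w <- .welch_epochs(es, seg_s, overlap)
  sel <- w$freq >= band@low & w$freq < band@high
  stats::setNames(rowSums(w$density[, sel, drop = FALSE]) * w$df,
                  es@channelLabels)
}

#' Differential entropy of band-filtered epochs
#'
#' Gaussian closed form: DE = 1/2 log(2 pi e sigma^2) in nats, with sigma^2
#' the sample variance of each band-filtered epoch, averaged across epochs.
#' For band-filtered EEG, which is well approximated as Gaussian, this is a
#' logarithmic band-power feature.
#'
#' @param es band-filtered [EpochSet-class]
#' @return named per-channel DE vector (nats)
#' @export
differentialEntropy <- function(es) {
  stopifnot(is(es, "EpochSet"))
  if (is.null(es@band))
    stop("differential entropy is defined per band; apply bandFilter() first")
  d <- dim(es@epochs)
  v <- apply(es@epochs, c(1, 2), stats::var)
  if (any(v <= 0))
    stop("zero-variance epoch: differential entropy is degenerate")
  de <- 0.5 * log(2 * pi * exp(1) * v)
  stats::setNames(colMeans(de), es@channelLabels)
}

.check_aligned <- function(delta, beta) {
  if (!identical(dim(delta@phase), dim(beta@amplitude)))
    stop("delta and beta analytic signals are not aligned in epochs/samples")
}

#' Debiased phase-amplitude coupling (delta phase -> beta envelope)
#'
#' Per channel, with phi the slow-band phase and a the fast-band envelope
#' over all concatenated epoch samples:
#' dPAC = | mean(a * exp(i phi)) - mean(a) * mean(exp(i phi)) |,
#' the amplitude-weighted mean phase vector with the phase-clustering bias
#' (the unweighted mean phase vector) subtracted. With `normalize = TRUE`
#' the modulus is divided by the mean envelope, giving a dimensionless
#' coupling index.
#'
#' @param delta [AnalyticSignal-class] providing the phase (slow band)
#' @param beta [AnalyticSignal-class] providing the envelope (fast band)
#' @param normalize divide by the mean envelope (default FALSE)
#' @return named per-channel dPAC vector
#' @export
dpac <- function(delta, beta, normalize = FALSE) {
  .check_aligned(delta, beta)
  d <- dim(delta@phase)
  out <- numeric(d[2])
  for (ch in seq_len(d[2])) {
    phi <- as.numeric(delta@phase[, ch, ])
    a <- as.numeric(beta@amplitude[, ch, ])
    z <- exp(1i * phi)
    v <- Mod(mean(a * z) - mean(a) * mean(z))
    out[ch] <- if (normalize) v / mean(a) else v
  }
  stats::setNames(out, delta@channelLabels)
}

#' Amplitude-amplitude coupling (delta vs beta envelope correlation)
#'
#' Pearson correlation between the slow-band and fast-band Hilbert
#' envelopes, per channel, over all concatenated epoch samples.
#'
#' @inheritParams dpac
#' @return named per-channel AAC vector in [-1, 1]
#' @export
aac <- function(delta, beta) {
  .check_aligned(delta, beta)
  d <- dim(delta@phase)
  out <- numeric(d[2])
  for (ch in seq_len(d[2])) {
    a1 <- as.numeric(delta@amplitude[, ch, ])
    a2 <- as.numeric(beta@amplitude[, ch, ])
    if (stats::sd(a1) == 0 || stats::sd(a2) == 0)
      stop("constant envelope: amplitude-amplitude coupling is undefined")
    out[ch] <- stats::cor(a1, a2)
  }
  stats::setNames(out, delta@channelLabels)
}

# The 12 per-channel feature families for one preprocessed broadband EpochSet:
# 5-band PSD, 5-band DE, AAC and dPAC. Returns a families x channels matrix.
.epochset_features <- function(es, bands = canonicalBands(),
                               dpac_normalize = FALSE) {
  nch <- length(es@channelLabels)
  out <- matrix(NA_real_, length(.FEATURE_FAMILIES), nch,
                dimnames = list(.FEATURE_FAMILIES, es@channelLabels))
  w <- .welch_epochs(es)
  banded <- lapply(bands, function(bd) bandFilter(es, bd))
  for (bn in names(bands)) {
    bd <- bands[[bn]]
    sel <- w$freq >= bd@low & w$freq < bd@high
    out[paste0("psd_", bn), ] <- rowSums(w$density[, sel, drop = FALSE]) * w$df
    out[paste0("de_", bn), ] <- differentialEntropy(banded[[bn]])
  }
  dl <- analyticSignal(banded[["delta"]])
  bt <- analyticSignal(banded[["beta"]])
  out["aac", ] <- aac(dl, bt)
  out["dpac", ] <- dpac(dl, bt, normalize = dpac_normalize)
  out
}

#' Build the subjects-by-features matrix for one paradigm
#'
#' Runs the preprocessing chain (average re-reference, 1-49 Hz bandpass +
#' 50 Hz notch, 6-s epoching) on each subject's recording and extracts the
#' twelve per-channel feature families: band PSD and differential entropy
#' for delta, theta, alpha, beta and gamma, plus delta-beta AAC and dPAC.
#' With 19 channels this yields 228 features per subject, in a deterministic
#' order (family-major, montage order within family).
#'
#' @param recs list of [Recording-class], one per subject, same paradigm
#' @param metadata data.frame with columns `subject_id`, `group` and
#'   optionally the cognitive scores `TMT_A`, `TMT_B`, `DST`, `SDMT`
#' @param epoch_s epoch length in seconds (default 6)
#' @param bands band table (default [canonicalBands()])
#' @param preprocess apply the re-reference + broadband filter front end
#'   (default TRUE; set FALSE if recordings are already preprocessed)
#' @param dpac_normalize passed to [dpac()]
#' @return a [FeatureMatrix-class] (features x subjects)
#' @export
buildFeatureMatrix <- function(recs, metadata, epoch_s = 6,
                               bands = canonicalBands(), preprocess = TRUE,
                               dpac_normalize = FALSE) {
  stopifnot(length(recs) >= 1, all(vapply(recs, is, logical(1), "Recording")))
  ids <- vapply(recs, subjectId, character(1))
  paradigm <- unique(vapply(recs, paradigmOf, character(1)))
  if (length(paradigm) != 1)
    stop("all recordings must belong to one paradigm")
  cols <- list()
  kept <- character(0)
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    if (preprocess) rec <- filterBroadband(rereferenceAverage(rec))
    if (ncol(rec@data) < epoch_s * rec@fs) {
      warning(sprintf("subject %s: no complete %g-s epoch; excluded",
                      ids[i], epoch_s))
      next
    }
    es <- segmentEpochs(rec, epoch_s)
    f <- .epochset_features(es, bands, dpac_normalize)
    cols[[length(cols) + 1L]] <- as.numeric(t(f))
    kept <- c(kept, ids[i])
  }
  if (!length(cols)) stop("no subject yielded a complete epoch")
  nch <- length(recs[[1]]@channelLabels)
  assay <- do.call(cbind, cols)
  rowdat <- S4Vectors::DataFrame(
    family = rep(.FEATURE_FAMILIES, each = nch),
    channel = rep(recs[[1]]@channelLabels, times = length(.FEATURE_FAMILIES)))
  rownames(assay) <- paste(rowdat$family, rowdat$channel, sep = "_")
  colnames(assay) <- kept
  md <- metadata[match(kept, metadata$subject_id), , drop = FALSE]
  if (anyNA(md$subject_id))
    stop("metadata is missing entries for some recorded subjects")
  cd <- S4Vectors::DataFrame(md)
  cd$paradigm <- paradigm
  rownames(cd) <- kept
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay), rowData = rowdat, colData = cd)
  new("FeatureMatrix", se)
}

#' Extract the subjects x features design matrix
#'
#' Transposes the feature assay into the classifier orientation (one row
#' per subject).
#'
#' @param fm a [FeatureMatrix-class]
#' @return numeric matrix subjects x features
#' @export
featureDesign <- function(fm) {
  t(SummarizedExperiment::assay(fm, "features"))
}

#' Group labels of a feature matrix
#' @param fm a [FeatureMatrix-class]
#' @return factor with levels HC, BD (BD last = positive class)
#' @export
groupLabels <- function(fm) {
  factor(SummarizedExperiment::colData(fm)$group, levels = c("HC", "BD"))
}
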