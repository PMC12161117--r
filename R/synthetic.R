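#' @include AllClasses.R dsp.R preprocess.R
NULL

.GROUPS <- c("BD", "HC")
.SCORES <- c("TMT_A", "TMT_B", "DST", "SDMT")

# Bands used for signal synthesis. Gamma is generated only up to 45 Hz so the
# 49 Hz broadband low-pass does not truncate it asymmetrically.
.generationBands <- function() {
  b <- canonicalBands()
  b$gamma <- bandDefinition("gamma", 30, 45)
  b
}

#' Parameterisation of a synthetic two-group EEG cohort
#'
#' Everything the generator needs to synthesise a bipolar-depression (BD)
#' vs healthy-control (HC) cohort with known ground truth: group sizes,
#' montage, sampling rate and duration; per-group band oscillation
#' amplitudes; a pairwise coupling graph (shared narrowband sources with a
#' fixed phase lag, injected with a given strength); delta-phase modulation
#' depth of the beta envelope (cross-frequency coupling); and a linear model
#' mapping each subject's realized delta/theta log band power to the four
#' cognitive scores.
#'
#' @slot nBD,nHC group sizes
#' @slot channels montage labels
#' @slot fs sampling rate (samples/s)
#' @slot duration seconds per paradigm
#' @slot bandAmplitudes list(BD=, HC=) of named band RMS amplitudes (uV)
#' @slot subjectSd log-scale SD of per-subject band amplitude multipliers
#' @slot oneOverFScale RMS amplitude (uV) of the 1/f background
#' @slot couplingEdges data.frame(paradigm, group, chA, chB, band, lag,
#'   strength): shared-source coupling graph; strength in [0,1], lag in rad
#' @slot pacDepth named numeric c(BD=, HC=): beta-envelope modulation depth
#'   kappa in [0,1] by delta phase
#' @slot paradigmOverrides named list (paradigm -> list that may carry
#'   bandAmplitudes and/or pacDepth) overriding the base values
#' @slot cognitionModel 4 x 4 matrix (rows TMT_A, TMT_B, DST, SDMT; columns
#'   intercept, delta, theta, sd): score = b0 + b_d * z_delta + b_t * z_theta
#'   + N(0, sd), with z the centred realized log band powers
#' @slot paradigms paradigms to generate
#' @slot seed master seed; per-subject streams are derived by a counter
#' @export
setClass("CohortSpec",
  representation(nBD = "integer", nHC = "integer", channels = "character",
                 fs = "numeric", duration = "numeric",
                 bandAmplitudes = "list", subjectSd = "numeric",
                 oneOverFScale = "numeric", couplingEdges = "data.frame",
                 pacDepth = "numeric", paradigmOverrides = "list",
                 cognitionModel = "matrix", paradigms = "character",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@nBD < 2L || object@nHC < 2L)
    return("each group needs at least 2 subjects")
  bands <- .generationBands()
  top <- max(vapply(bands, function(b) b@high, numeric(1)))
  if (object@fs <= 2 * top)
    return(sprintf("fs must exceed twice the highest band edge (%g Hz)", top))
  if (object@duration * object@fs < 6 * object@fs)
    return("duration must allow at least one full 6-s epoch")
  if (!all(.GROUPS %in% names(object@bandAmplitudes)))
    return("bandAmplitudes must have entries 'BD' and 'HC'")
  ce <- object@couplingEdges
  if (nrow(ce)) {
    if (!all(c("paradigm", "group", "chA", "chB", "band", "lag", "strength")
             %in% colnames(ce)))
      return("couplingEdges lacks required columns")
    if (any(ce$strength < 0 | ce$strength > 1))
      return("coupling strength must lie in [0,1]")
    miss <- setdiff(unique(c(ce$chA, ce$chB)), object@channels)
    if (length(miss))
      return(sprintf("coupling edge channel(s) not in montage: %s",
                     paste(miss, collapse = ", ")))
  }
  if (any(object@pacDepth < 0 | object@pacDepth > 1))
    return("pacDepth must lie in [0,1]")
  if (!all(rownames(object@cognitionModel) == .SCORES) ||
      !all(colnames(object@cognitionModel) ==
             c("intercept", "delta", "theta", "sd")))
    return("cognitionModel must be 4x4 with score rows and (intercept, delta, theta, sd) columns")
  TRUE
})

.default_edges <- function() {
  e <- function(paradigm, group, chA, chB, band, lag, strength)
    data.frame(paradigm = paradigm, group = group, chA = chA, chB = chB,
               band = band, lag = lag, strength = strength)
  base <- rbind(
    # eyes closed: BD shows stronger coupling in delta, theta, beta, gamma;
    # alpha identical across groups
    e("eyes_closed", "BD", c("FP1", "FP2", "F3", "F4"),
      c("O1", "O2", "O1", "O2"), "delta", pi / 4, 0.55),
    e("eyes_closed", "HC", c("FP1", "FP2", "F3", "F4"),
      c("O1", "O2", "O1", "O2"), "delta", pi / 4, 0.25),
    e("eyes_closed", "BD", c("P3", "P4", "FZ"), c("O1", "O2", "PZ"),
      "theta", pi / 5, 0.50),
    e("eyes_closed", "HC", c("P3", "P4", "FZ"), c("O1", "O2", "PZ"),
      "theta", pi / 5, 0.25),
    e("eyes_closed", c("BD", "HC"), "O1", "O2", "alpha", pi / 6, 0.35),
    e("eyes_closed", c("BD", "HC"), "P3", "P4", "alpha", pi / 6, 0.35),
    e("eyes_closed", "BD", c("F3", "F4"), c("P3", "P4"), "beta", pi / 4, 0.45),
    e("eyes_closed", "HC", c("F3", "F4"), c("P3", "P4"), "beta", pi / 4, 0.20),
    e("eyes_closed", "BD", c("FP1", "O1"), c("FP2", "O2"), "gamma",
      pi / 4, 0.40),
    e("eyes_closed", "HC", c("FP1", "O1"), c("FP2", "O2"), "gamma",
      pi / 4, 0.20),
    # eyes open: same coupling graph in both groups (no group effect)
    e("eyes_open", c("BD", "HC"), c("FP1", "FP2"), c("O1", "O2"),
      "delta", pi / 4, 0.25),
    e("eyes_open", c("BD", "HC"), "O1", "O2", "alpha", pi / 6, 0.25),
    # free viewing: BD shows weaker delta/theta long-range coupling
    e("free_viewing", "BD", c("F3", "F4"), c("P3", "P4"), "delta",
      pi / 4, 0.20),
    e("free_viewing", "HC", c("F3", "F4"), c("P3", "P4"), "delta",
      pi / 4, 0.45),
    e("free_viewing", "BD", c("FZ", "P3"), c("PZ", "O1"), "theta",
      pi / 5, 0.20),
    e("free_viewing", "HC", c("FZ", "P3"), c("PZ", "O1"), "theta",
      pi / 5, 0.40))
  base
}

.default_cognition <- function() {
  m <- rbind(TMT_A = c(27, 0, 4, 5),
             TMT_B = c(38, 6, 3, 6),
             DST   = c(13, -2, 0, 1.5),
             SDMT  = c(68, -6, 0, 8))
  colnames(m) <- c("intercept", "delta", "theta", "sd")
  m
}

#' Construct a cohort specification
#'
#' Defaults emulate the study conditions the analysis assumes: 28 BD and 42
#' HC subjects, the 19-channel 10-20 montage at 250 Hz, 180 s per paradigm,
#' band-limited oscillations over a 1/f background, group-dependent
#' phase-lagged coupling (stronger BD coupling in delta/theta/beta/gamma
#' with eyes closed, no group difference with eyes open, weaker BD
#' delta/theta coupling during free viewing), stronger delta-phase
#' modulation of the beta envelope in BD, and cognitive scores linearly
#' tied to realized delta/theta log power.
#'
#' @param nBD,nHC group sizes (defaults 28 and 42)
#' @param channels montage (default [montage19()])
#' @param fs sampling rate, samples/s (default 250)
#' @param duration seconds per paradigm (default 180)
#' @param bandAmplitudes list(BD=, HC=) named band RMS amplitudes in uV
#' @param subjectSd per-subject log-amplitude SD (default 0.3)
#' @param oneOverFScale 1/f background RMS in uV (default 8)
#' @param couplingEdges coupling graph data.frame (see [CohortSpec-class])
#' @param pacDepth named numeric c(BD=, HC=) modulation depths
#' @param paradigmOverrides per-paradigm parameter overrides
#' @param cognitionModel 4x4 coefficient matrix (see [CohortSpec-class])
#' @param paradigms paradigms to generate
#' @param seed master seed
#' @return a validated [CohortSpec-class]
#' @export
cohortSpec <- function(nBD = 28L, nHC = 42L, channels = montage19(),
                       fs = 250, duration = 180,
                       bandAmplitudes = NULL, subjectSd = 0.3,
                       oneOverFScale = 8,
                       couplingEdges = .default_edges(),
                       pacDepth = c(BD = 0.4, HC = 0.15),
                       paradigmOverrides = list(),
                       cognitionModel = .default_cognition(),
                       paradigms = .PARADIGMS, seed = 1L) {
  if (is.null(bandAmplitudes)) {
    amps <- c(delta = 8, theta = 5, alpha = 10, beta = 3, gamma = 1.5)
    bandAmplitudes <- list(BD = amps, HC = amps)
  }
  new("CohortSpec", nBD = as.integer(nBD), nHC = as.integer(nHC),
      channels = toupper(channels), fs = fs, duration = duration,
      bandAmplitudes = bandAmplitudes, subjectSd = subjectSd,
      oneOverFScale = oneOverFScale, couplingEdges = couplingEdges,
      pacDepth = pacDepth, paradigmOverrides = paradigmOverrides,
      cognitionModel = cognitionModel, paradigms = paradigms,
      seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0("CohortSpec: %d BD + %d HC, %d channels @ %g Hz, ",
                     "%g s x {%s}\n  %d coupling edges, pacDepth BD=%.2f ",
                     "HC=%.2f, seed %d\n"),
              object@nBD, object@nHC, length(object@channels), object@fs,
              object@duration, paste(object@paradigms, collapse = ", "),
              nrow(object@couplingEdges), object@pacDepth["BD"],
              object@pacDepth["HC"], object@seed))
})

# Effective parameters for (group, paradigm) after overrides.
.effective_params <- function(spec, group, paradigm) {
  amps <- spec@bandAmplitudes[[group]]
  kappa <- unname(spec@pacDepth[group])
  ov <- spec@paradigmOverrides[[paradigm]]
  if (!is.null(ov)) {
    if (!is.null(ov$bandAmplitudes)) amps <- ov$bandAmplitudes[[group]]
    if (!is.null(ov$pacDepth)) kappa <- unname(ov$pacDepth[group])
  }
  ce <- spec@couplingEdges
  edges <- ce[ce$group == group & ce$paradigm == paradigm, , drop = FALSE]
  list(amps = amps, kappa = kappa, edges = edges)
}

# Unit-RMS narrowband noise processes: rows x n matrix.
.narrowband_rows <- function(nrows, n, band, fs) {
  bp <- .butter_bandpass(band@low, band@high, fs, 4L)
  npad <- min(round(fs), n - 1L)
  out <- .filtfilt_rows(bp$b, bp$a, matrix(stats::rnorm(nrows * n), nrows, n),
                        npad)
  out / sqrt(rowMeans(out^2))
}

# Fractional-sample delay via the frequency domain: shift x by tau seconds.
.fractional_delay <- function(x, tau, fs) {
  n <- length(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  Re(stats::fft(stats::fft(x) * exp(-2i * pi * f * tau), inverse = TRUE) / n)
}

# 1/f (pink) background, unit RMS rows, synthesized by spectral shaping with
# exponent 1 (power ~ 1/f, flat below 1 Hz to avoid the DC singularity).
# The spectrum is drawn directly as a Hermitian complex-Gaussian half
# spectrum so one inverse FFT per row yields the real signal.
.pink_rows <- function(nrows, n, fs) {
  h <- floor(n / 2)
  f <- c(seq(0, h), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  shape <- 1 / sqrt(pmax(abs(f), 1))
  shape[1] <- 0
  Z <- matrix(0i, n, nrows)
  npos <- h - 1L
  Z[2:h, ] <- matrix(complex(real = stats::rnorm(npos * nrows),
                             imaginary = stats::rnorm(npos * nrows)),
                     npos, nrows)
  Z[h + 1L, ] <- complex(real = stats::rnorm(nrows))
  if (n %% 2 == 1) Z[h + 1L, ] <- Z[h + 1L, ] + 1i * stats::rnorm(nrows)
  idx <- seq(n, h + 2L)
  Z[idx, ] <- Conj(Z[2:(n - h), ])
  Y <- Re(stats::mvfft(Z * shape, inverse = TRUE)) / n
  out <- t(Y)
  out / sqrt(rowMeans(out^2))
}

#' Generate one synthetic subject recording
#'
#' Synthesises a channels x samples EEG signal as a sum over bands of
#' narrowband Gaussian processes (white noise band-filtered so phases drift
#' realistically) over a 1/f background. For every coupling edge a shared
#' narrowband source is injected into both channels, the second copy delayed
#' in the frequency domain by `lag / (2 pi f_center)` seconds and mixed with
#' weight `strength` (variance-preserving: `sqrt(1 - strength^2)` own
#' process + `strength` shared source). The beta-band component's envelope
#' is scaled by `(1 + kappa cos(delta phase))`, normalised to preserve the
#' band RMS. Deterministic given `seed`.
#'
#' @param spec a [CohortSpec-class]
#' @param group `"BD"` or `"HC"`
#' @param seed integer seed for this subject
#' @param paradigm paradigm label
#' @param subjectId subject identifier for the returned object
#' @return a [Recording-class]
#' @export
generateSubject <- function(spec, group, seed, paradigm = "eyes_closed",
                            subjectId = sprintf("%s01", group)) {
  stopifnot(is(spec, "CohortSpec"))
  if (!group %in% .GROUPS)
    stop(sprintf("invalid group label '%s' (expected BD or HC)", group))
  if (spec@duration <= 0) stop("non-positive duration")
  set.seed(as.integer(seed))
  n <- round(spec@duration * spec@fs)
  nch <- length(spec@channels)
  par <- .effective_params(spec, group, paradigm)
  bands <- .generationBands()
  # per-subject band amplitude multipliers (trait-like power variation)
  mult <- exp(stats::rnorm(length(bands), 0, spec@subjectSd))
  names(mult) <- names(bands)
  comp <- list()
  for (bn in names(bands)) {
    amp <- unname(par$amps[bn]) * mult[[bn]]
    be <- par$edges[par$edges$band == bn, , drop = FALSE]
    if (amp == 0 && nrow(be) == 0) next  # band contributes nothing
    own <- .narrowband_rows(nch, n, bands[[bn]], spec@fs)
    if (nrow(be)) {
      f0 <- (bands[[bn]]@low + bands[[bn]]@high) / 2
      for (j in seq_len(nrow(be))) {
        w <- be$strength[j]
        src <- as.numeric(.narrowband_rows(1L, n, bands[[bn]], spec@fs))
        tau <- be$lag[j] / (2 * pi * f0)
        lagged <- .fractional_delay(src, tau, spec@fs)
        lagged <- lagged / sqrt(mean(lagged^2))
        ia <- match(toupper(be$chA[j]), spec@channels)
        ib <- match(toupper(be$chB[j]), spec@channels)
        own[ia, ] <- sqrt(1 - w^2) * own[ia, ] + w * src
        own[ib, ] <- sqrt(1 - w^2) * own[ib, ] + w * lagged
      }
    }
    comp[[bn]] <- amp * own
  }
  if (par$kappa > 0 && !is.null(comp$delta) && !is.null(comp$beta)) {
    z <- .analytic_cols(t(comp$delta))
    phi <- t(Arg(z))
    mod <- (1 + par$kappa * cos(phi)) / sqrt(1 + par$kappa^2 / 2)
    comp$beta <- comp$beta * mod
  }
  x <- Reduce(`+`, comp, accumulate = FALSE)
  if (is.null(x)) x <- matrix(0, nch, n)
  if (spec@oneOverFScale > 0)
    x <- x + spec@oneOverFScale * .pink_rows(nch, n, spec@fs)
  recording(x, fs = spec@fs, channelLabels = spec@channels,
            subjectId = subjectId, paradigm = paradigm)
}

#' Generate a full two-group cohort with ground truth
#'
#' Generates `nBD + nHC` subjects for every paradigm in the spec, each from
#' an independent seed stream derived from the master seed by a counter.
#' Cognitive scores are drawn from the cognition model given each subject's
#' realized (not nominal) eyes-closed delta and theta log band power, so the
#' score-power correlation survives downstream re-estimation. Demographics
#' (age, sex) are drawn to resemble a young clinical cohort.
#'
#' @param spec a [CohortSpec-class]
#' @return list with elements `recordings` (list: paradigm -> list of
#'   [Recording-class]), `metadata` (data.frame: subject_id, group, age,
#'   sex, TMT_A, TMT_B, DST, SDMT) and `groundTruth` (list: coupling edge
#'   table, per-subject pac depth, per-subject latent log-power drivers)
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  groups <- c(rep("BD", spec@nBD), rep("HC", spec@nHC))
  ids <- sprintf("%s%02d", groups, c(seq_len(spec@nBD), seq_len(spec@nHC)))
  nsub <- length(ids)
  recordings <- lapply(spec@paradigms, function(p) vector("list", nsub))
  names(recordings) <- spec@paradigms
  drivers <- data.frame(subject_id = ids, log_delta = NA_real_,
                        log_theta = NA_real_)
  counter <- 0L
  for (pi_ in seq_along(spec@paradigms)) {
    p <- spec@paradigms[pi_]
    for (s in seq_len(nsub)) {
      counter <- counter + 1L
      rec <- generateSubject(spec, groups[s],
                             seed = .substream_seed(spec@seed, counter),
                             paradigm = p, subjectId = ids[s])
      recordings[[p]][[s]] <- rec
      if (pi_ == 1L) {
        # realized log band power of the driver bands, mean over channels
        for (bn in c("delta", "theta")) {
          bd <- .generationBands()[[bn]]
          bp <- .butter_bandpass(bd@low, bd@high, spec@fs, 4L)
          y <- .filtfilt_rows(bp$b, bp$a, rec@data,
                              min(round(spec@fs), ncol(rec@data) - 1L))
          drivers[[paste0("log_", bn)]][s] <- log(mean(rowMeans(y^2)))
        }
      }
    }
    names(recordings[[p]]) <- ids
  }
  set.seed(.substream_seed(spec@seed, counter + 1L))
  age <- ifelse(groups == "BD", stats::rnorm(nsub, 21.1, 4.4),
                stats::rnorm(nsub, 22.9, 2.1))
  sex <- ifelse(stats::runif(nsub) < ifelse(groups == "BD", 20 / 28, 25 / 42),
                "F", "M")
  md <- data.frame(subject_id = ids, group = groups,
                   age = round(pmax(age, 16), 1), sex = sex)
  zd <- drivers$log_delta - mean(drivers$log_delta)
  zt <- drivers$log_theta - mean(drivers$log_theta)
  cm <- spec@cognitionModel
  for (sc in .SCORES) {
    md[[sc]] <- cm[sc, "intercept"] + cm[sc, "delta"] * zd +
      cm[sc, "theta"] * zt + stats::rnorm(nsub, 0, cm[sc, "sd"])
  }
  gt <- list(couplingEdges = spec@couplingEdges,
             pacDepth = stats::setNames(unname(spec@pacDepth[groups]), ids),
             drivers = drivers)
  list(recordings = recordings, metadata = md, groundTruth = gt)
}

#' Streamed per-subject connectivity for a synthetic cohort
#'
#' Generates each subject in turn (same seed streams as [generateCohort()])
#' and immediately reduces the recording to its [ConnectivityTensor-class],
#' so a full-size cohort never has to be held in memory. Used for
#' parameter-recovery studies of the connectivity statistics.
#'
#' @param spec a [CohortSpec-class] (its first paradigm is generated)
#' @param bands band table for the PLI tensors (default all five)
#' @param preprocess apply the broadband front-end before epoching; with
#'   clean synthetic input (no drift or line noise) this is a near no-op
#'   and may be disabled for speed
#' @return list with `tensors` (per subject) and `groups` (label vector)
#' @export
cohortConnectivity <- function(spec, bands = canonicalBands(),
                               preprocess = FALSE) {
  stopifnot(is(spec, "CohortSpec"))
  groups <- c(rep("BD", spec@nBD), rep("HC", spec@nHC))
  p <- spec@paradigms[1]
  tensors <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    rec <- generateSubject(spec, groups[s], seed = .substream_seed(spec@seed, s),
                           paradigm = p, subjectId = sprintf("S%02d", s))
    rec <- rereferenceAverage(rec)
    if (preprocess) rec <- filterBroadband(rec)
    tensors[[s]] <- connectivityTensor(segmentEpochs(rec), bands)
  }
  list(tensors = tensors, groups = groups)
}

#' Write a generated cohort to disk
#'
#' One signal file per subject and paradigm (tab-separated matrix layout or
#' EDF), `metadata.tsv` with file paths and `ground_truth.json`.
#'
#' @param cohort result of [generateCohort()]
#' @param dir output directory (created if needed)
#' @param format `"matrix"` or `"edf"`
#' @return `dir`, invisibly
#' @export
writeCohort <- function(cohort, dir, format = c("matrix", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- cohort$metadata
  ext <- if (format == "edf") "edf" else "tsv"
  for (p in names(cohort$recordings)) {
    col <- paste0("file_", p)
    md[[col]] <- NA_character_
    for (s in seq_along(cohort$recordings[[p]])) {
      rec <- cohort$recordings[[p]][[s]]
      fn <- sprintf("%s_%s.%s", rec@subjectId, p, ext)
      path <- file.path(dir, fn)
      if (format == "edf") writeRecordingEDF(rec, path)
      else writeRecordingMatrix(rec, path)
      md[[col]][match(rec@subjectId, md$subject_id)] <- fn
    }
  }
  utils::write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$groundTruth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
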