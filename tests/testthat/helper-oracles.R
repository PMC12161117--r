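# Independent oracles and small builders shared across the test files.

# Brute-force PLI: literal per-sample evaluation of
# |(1/M) sum_m sgn(wrapped phase difference)| with per-epoch time averaging,
# written with scalar loops so it shares no code with pliMatrix().
bruteForcePli <- function(ph) {
  wrap1 <- function(d) d - 2 * pi * ceiling((d - pi) / (2 * pi))
  sgn1 <- function(v) if (v > 0) 1 else if (v < 0) -1 else 0
  nep <- dim(ph)[1]; nch <- dim(ph)[2]; ns <- dim(ph)[3]
  out <- matrix(0, nch, nch)
  for (a in seq_len(nch - 1)) {
    for (b in (a + 1):nch) {
      em <- numeric(nep)
      for (k in seq_len(nep)) {
        s <- 0
        for (t in seq_len(ns)) s <- s + sgn1(wrap1(ph[k, a, t] - ph[k, b, t]))
        em[k] <- s / ns
      }
      out[a, b] <- out[b, a] <- abs(mean(em))
    }
  }
  out
}

# Wrap a phase (and optional amplitude) array into an AnalyticSignal.
mkAnalytic <- function(phase, amplitude = NULL, band = canonicalBands()$alpha,
                       fs = 250, labels = NULL) {
  if (is.null(amplitude)) amplitude <- array(1, dim(phase))
  if (is.null(labels)) labels <- sprintf("CH%02d", seq_len(dim(phase)[2]))
  new("AnalyticSignal", phase = phase, amplitude = amplitude, fs = fs,
      channelLabels = labels, band = band)
}

# Directly assembled FeatureMatrix (bypasses signal processing): standard
# normal features, optional mean shift on selected rows for the BD group.
mkFeatureMatrix <- function(nBD = 14, nHC = 21, shift = 0,
                            shiftRows = integer(0), seed = 1,
                            families = eegparadigm:::.FEATURE_FAMILIES,
                            channels = montage19(), scores = TRUE) {
  set.seed(seed)
  groups <- c(rep("BD", nBD), rep("HC", nHC))
  ids <- sprintf("%s%02d", groups, c(seq_len(nBD), seq_len(nHC)))
  nf <- length(families) * length(channels)
  X <- matrix(rnorm(nf * length(ids)), nf, length(ids))
  if (length(shiftRows)) X[shiftRows, groups == "BD"] <-
    X[shiftRows, groups == "BD"] + shift
  rd <- S4Vectors::DataFrame(family = rep(families, each = length(channels)),
                             channel = rep(channels, length(families)))
  rownames(X) <- paste(rd$family, rd$channel, sep = "_")
  colnames(X) <- ids
  cd <- S4Vectors::DataFrame(subject_id = ids, group = groups,
                             paradigm = "eyes_closed", row.names = ids)
  if (scores) {
    cd$TMT_A <- rnorm(length(ids), 27, 5)
    cd$TMT_B <- rnorm(length(ids), 38, 6)
    cd$DST <- rnorm(length(ids), 13, 2)
    cd$SDMT <- rnorm(length(ids), 68, 8)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = X), rowData = rd, colData = cd)
  new("FeatureMatrix", se)
}

# Hand-built two-channel EDF file written byte by byte from the format
# definition, independent of the package's EDF writer. Signal CH1 carries
# digital values 0, 1000, -1000, 32767 at gain 0.001 (phys -32.768..32.767
# over digital -32768..32767), CH2 carries 100, 200, 300, 400.
writeTinyEDF <- function(path) {
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) writeChar(formatC(as.character(x), width = -w),
                                  con, eos = NULL)
  pad("0", 8); pad("T01", 80); pad("tiny", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(256 * 3, 8); pad("", 44)
  pad(1, 8)      # 1 data record
  pad(1, 8)      # of 1 second
  pad(2, 4)      # 2 signals
  pad("CH1", 16); pad("CH2", 16)
  pad("", 80); pad("", 80)
  pad("uV", 8); pad("uV", 8)
  pad("-32.768", 8); pad("-32.768", 8)
  pad("32.767", 8); pad("32.767", 8)
  pad("-32768", 8); pad("-32768", 8)
  pad("32767", 8); pad("32767", 8)
  pad("", 80); pad("", 80)
  pad(4, 8); pad(4, 8)   # 4 samples per record -> fs = 4 Hz
  pad("", 32); pad("", 32)
  writeBin(as.integer(c(0L, 1000L, -1000L, 32767L)), con, size = 2,
           endian = "little")
  writeBin(as.integer(c(100L, 200L, 300L, 400L)), con, size = 2,
           endian = "little")
  invisible(path)
}

# Classic Benjamini-Hochberg step-up REJECTION SET (not adjusted p-values):
# largest k with p_(k) <= k q / n, reject the k smallest.
stepUpReject <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(n) / n)
  rej <- logical(n)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}
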