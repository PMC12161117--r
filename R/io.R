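#' @include AllClasses.R
NULL

# --- minimal European Data Format (EDF) support -----------------------------
# Fixed-layout 256-byte header + 256 bytes per signal, then data records of
# 2-byte little-endian integers, linearly scaled between the digital and
# physical ranges declared in the header.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

.edf_num <- function(x, width) .edf_pad(format(x, trim = TRUE, digits = 7), width)

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  version <- hdr(8)
  patient <- hdr(80); rec_id <- hdr(80)
  startdate <- hdr(8); starttime <- hdr(8)
  nbytes_header <- as.integer(hdr(8))
  reserved <- hdr(44)
  n_records <- as.integer(hdr(8))
  record_s <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: no signals")
  fld <- function(w) vapply(seq_len(ns), function(i) hdr(w), character(1))
  labels <- fld(16)
  transducer <- fld(80); phys_dim <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  prefilter <- fld(80)
  nsamp_rec <- as.integer(fld(8))
  fld(32)  # per-signal reserved
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- vector("list", ns)
  for (i in seq_len(ns)) data[[i]] <- numeric(n_records * nsamp_rec[i])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nsamp_rec[i], size = 2,
                     signed = TRUE, endian = "little")
      data[[i]][((r - 1L) * nsamp_rec[i] + 1L):(r * nsamp_rec[i])] <-
        phys_min[i] + (raw - dig_min[i]) * gain[i]
    }
  }
  fs <- nsamp_rec / record_s
  if (length(unique(fs)) > 1)
    stop("EDF signals with heterogeneous sampling rates are not supported")
  mat <- do.call(rbind, data)
  rownames(mat) <- labels
  list(data = mat, fs = fs[1], labels = labels, subject = patient)
}

.write_edf <- function(path, data, fs, labels, subject = "X") {
  ns <- nrow(data)
  record_s <- 1
  nsamp_rec <- round(fs * record_s)
  n_records <- floor(ncol(data) / nsamp_rec)
  data <- data[, seq_len(n_records * nsamp_rec), drop = FALSE]
  phys_min <- apply(data, 1, min) - 1e-6
  phys_max <- apply(data, 1, max) + 1e-6
  dig_min <- rep(-32768, ns); dig_max <- rep(32767, ns)
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x) writeChar(x, con, eos = NULL)
  put(.edf_pad("0", 8))
  put(.edf_pad(subject, 80)); put(.edf_pad("synthetic", 80))
  put(.edf_pad("01.01.26", 8)); put(.edf_pad("00.00.00", 8))
  put(.edf_num(256L * (1L + ns), 8))
  put(.edf_pad("", 44))
  put(.edf_num(n_records, 8)); put(.edf_num(record_s, 8)); put(.edf_num(ns, 4))
  putv <- function(vals, w) for (v in vals) put(.edf_pad(v, w))
  putv(labels, 16)
  putv(rep("", ns), 80); putv(rep("uV", ns), 8)
  putv(format(phys_min, digits = 7, trim = TRUE), 8)
  putv(format(phys_max, digits = 7, trim = TRUE), 8)
  putv(dig_min, 8); putv(dig_max, 8)
  putv(rep("", ns), 80)
  putv(rep(nsamp_rec, ns), 8); putv(rep("", ns), 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      seg <- data[i, ((r - 1L) * nsamp_rec + 1L):(r * nsamp_rec)]
      dig <- round(dig_min[i] + (seg - phys_min[i]) / gain[i])
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

# --- public interface -------------------------------------------------------

#' Read a multichannel EEG recording
#'
#' Reads either a European Data Format (EDF) file or a delimited numeric
#' matrix (one row per channel, first column the channel label,
#' tab-separated, no header). Channels are restricted and reordered to the
#' requested montage by case-insensitive label match; a missing montage
#' channel is an explicit error naming it.
#'
#' @param path file path
#' @param format `"edf"` or `"matrix"`
#' @param fs sampling rate in samples/s; required for the matrix format, and
#'   checked against the file header for EDF when supplied
#' @param channels montage to restrict/reorder to (default [montage19()]);
#'   `NULL` keeps all channels in file order
#' @param subjectId,paradigm metadata attached to the returned object
#' @return a [Recording-class]
#' @export
readRecording <- function(path, format = c("edf", "matrix"), fs = NULL,
                          channels = montage19(), subjectId = NULL,
                          paradigm = "eyes_closed") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "edf") {
    raw <- .read_edf(path)
    if (!is.null(fs) && abs(fs - raw$fs) > 1e-9)
      stop(sprintf("EDF sampling rate %g Hz does not match configured %g Hz",
                   raw$fs, fs))
    mat <- raw$data; labels <- raw$labels; fs <- raw$fs
    if (is.null(subjectId)) subjectId <- if (nzchar(raw$subject)) raw$subject else "S01"
  } else {
    if (is.null(fs)) stop("matrix format requires an explicit sampling rate 'fs'")
    tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    labels <- as.character(tab[[1]])
    mat <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    if (is.null(subjectId)) subjectId <- "S01"
  }
  labels_uc <- toupper(trimws(labels))
  if (!is.null(channels)) {
    want <- toupper(channels)
    idx <- match(want, labels_uc)
    if (anyNA(idx))
      stop(sprintf("recording is missing montage channel(s): %s",
                   paste(channels[is.na(idx)], collapse = ", ")))
    mat <- mat[idx, , drop = FALSE]
    labels_uc <- want
  }
  if (anyNA(mat) || any(!is.finite(mat)))
    stop("recording contains non-finite samples")
  recording(mat, fs = fs, channelLabels = labels_uc,
            subjectId = subjectId, paradigm = paradigm)
}

#' Write a recording
#'
#' `writeRecordingMatrix()` writes the tab-separated matrix layout read back
#' by [readRecording()] (`format = "matrix"`); `writeRecordingEDF()` writes a
#' single-rate EDF file with 1-s data records and 16-bit quantisation.
#'
#' @param rec a [Recording-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writeRecordingMatrix <- function(rec, path) {
  tab <- data.frame(label = rec@channelLabels,
                    format(rec@data, digits = 8, trim = TRUE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeRecordingMatrix
#' @export
writeRecordingEDF <- function(rec, path) {
  .write_edf(path, rec@data, rec@fs, rec@channelLabels, rec@subjectId)
}
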