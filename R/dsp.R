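#' @include AllClasses.R
NULL

# Wrap angles to (-pi, pi]. The right-closed convention matters for the PLI
# sign: a difference of exactly +pi counts as positive.
wrapPhase <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

# Butterworth bandpass design (coefficients via signal::butter).
.butter_bandpass <- function(low, high, fs, order = 4L) {
  nyq <- fs / 2
  if (high >= nyq)
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)", high, nyq))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

# Second-order IIR notch (constrained biquad), -3 dB bandwidth f0/Q.
.notch_biquad <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Steady-state initial filter state for a unit-step input: starting each
# filtfilt pass from state zi * x[1] removes the start-up transient that a
# DC-passing filter (notably the power-line notch) otherwise injects.
.filter_zi <- function(b, a) {
  nw <- max(length(a), length(b)) - 1L
  bb <- c(b, numeric(nw + 1L - length(b)))
  aa <- c(a, numeric(nw + 1L - length(a)))
  A <- rbind(-aa[2:(nw + 1L)], cbind(diag(1, nw - 1L), numeric(nw - 1L)))
  B <- bb[2:(nw + 1L)] - aa[2:(nw + 1L)] * bb[1]
  as.numeric(solve(diag(nw) - t(A), B))
}

# Zero-phase (forward-backward) IIR on a vector, with odd reflection padding
# of `npad` samples at each end to suppress edge transients.
.filtfilt_vec <- function(b, a, x, npad = NULL) {
  if (is.null(npad)) npad <- 3L * (max(length(a), length(b)) - 1L)
  as.numeric(.filtfilt_mat(b, a, .filter_zi(b, a), matrix(x, ncol = 1L),
                           as.integer(npad)))
}

# Apply zero-phase filter to each row of a channels x samples matrix.
.filtfilt_rows <- function(b, a, m, npad = NULL) {
  if (is.null(npad)) npad <- 3L * (max(length(a), length(b)) - 1L)
  .filtfilt_mat(b, a, .filter_zi(b, a), m, as.integer(npad), byrow = TRUE)
}

# Analytic signal of each column of a samples x k matrix via the frequency-
# domain Hilbert construction (positive frequencies doubled, negatives zeroed).
.analytic_cols <- function(m) {
  n <- nrow(m)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(m) * h, inverse = TRUE) / n
}

# Welch one-sided PSD estimate for one channel.
# Hamming-windowed segments of seg_s seconds with fractional overlap,
# periodograms averaged; density in signal-units^2 / Hz.
.welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  nseg <- round(seg_s * fs)
  nseg <- min(nseg, length(x))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- signal::hamming(nseg)
  U <- sum(w^2)
  nfreq <- floor(nseg / 2) + 1L
  segs <- vapply(starts, function(s) x[s:(s + nseg - 1L)] * w,
                 numeric(nseg))
  P <- abs(stats::mvfft(segs))^2 / (fs * U)
  P <- P[seq_len(nfreq), , drop = FALSE]
  scale <- rep(2, nfreq)
  scale[1] <- 1
  if (nseg %% 2 == 0) scale[nfreq] <- 1
  dens <- rowMeans(P) * scale
  list(freq = (seq_len(nfreq) - 1L) * fs / nseg, density = dens,
       df = fs / nseg)
}

# Deterministic per-subject seed stream: master seed plus a counter, folded
# into the 31-bit range R's RNG seeding accepts.
.substream_seed <- function(master, counter) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + counter) %% 2147483647)
}
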