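# Zero-phase windowed-sinc FIR filtering of epoched data.
#
# Kernels are odd-length Hamming-windowed sinc filters applied by a single
# centered (zero-phase) convolution with mirror-padded edges; convolution is
# done in one batched FFT across all channel/trial signals.

fir_lowpass_kernel <- function(fs, cutoff, n_taps) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  if (n_taps %% 2 == 0) stop("n_taps must be odd")
  m <- (n_taps - 1) / 2
  k <- -m:m
  fc <- cutoff / fs
  h <- 2 * fc * sinc(2 * fc * k)
  w <- 0.54 + 0.46 * cos(pi * k / m) # Hamming
  h <- h * w
  h / sum(h) # unit DC gain
}

fir_highpass_kernel <- function(fs, cutoff, n_taps) {
  h <- -fir_lowpass_kernel(fs, cutoff, n_taps)
  m <- (n_taps - 1) / 2
  h[m + 1] <- h[m + 1] + 1 # spectral inversion: delta - lowpass
  h
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

default_taps <- function(fs, n_samples, wanted) {
  nt <- min(wanted, n_samples - 1)
  if (nt %% 2 == 0) nt <- nt - 1
  if (nt < 5) stop("epoch too short for FIR filtering")
  as.integer(nt)
}

# filter every channel/trial signal of an epoched_data with a centered FIR
# kernel; mirror padding, batched FFT convolution
apply_fir_epochs <- function(x, kernel) {
  d <- dim(x$data)
  sig <- aperm(x$data, c(2, 1, 3))   # samples x channels x trials
  dim(sig) <- c(d[2], d[1] * d[3])
  out <- apply_fir_matrix(sig, kernel)
  dim(out) <- c(d[2], d[1], d[3])
  x$data <- aperm(out, c(2, 1, 3))
  x
}

# signals in columns
apply_fir_matrix <- function(sig, kernel) {
  ns <- nrow(sig)
  L <- length(kernel)
  m <- (L - 1) / 2
  if (m >= ns) stop("kernel longer than signal")
  # mirror padding (reflection without repeating the edge sample)
  top <- sig[seq(m + 1, 2, by = -1), , drop = FALSE]
  bot <- sig[seq(ns - 1, ns - m, by = -1), , drop = FALSE]
  padded <- rbind(top, sig, bot)
  np <- nrow(padded)
  nfft <- 2^ceiling(log2(np + L - 1))
  K <- stats::fft(c(kernel, numeric(nfft - L)))
  Fp <- stats::mvfft(rbind(padded,
                           matrix(0, nfft - np, ncol(padded))))
  conv <- Re(stats::mvfft(Fp * K, inverse = TRUE)) / nfft
  # centered (zero-phase) output: kernel delay m cancels the pad offset
  conv[seq(2 * m + 1, 2 * m + ns), , drop = FALSE]
}

#' Zero-phase FIR high-pass / low-pass filtering of epoched data
#'
#' `highpass_filter` implements the 100-Hz high-pass used by SSP-SIR to
#' expose broadband muscle activity; `lowpass_filter` is the 80-Hz
#' anti-neuronal-noise low-pass used when generating ground-truth data.
#' Both are Hamming-windowed sinc FIR filters applied as a single centered
#' convolution (zero phase) with mirror-padded epoch edges.
#'
#' @param x an `epoched_data`.
#' @param cutoff cutoff frequency in Hz (must be < fs/2).
#' @param n_taps odd FIR length; default scales with the sampling rate and
#'   is capped below the epoch length.
#' @return filtered `epoched_data`.
#' @export
highpass_filter <- function(x, cutoff = 100, n_taps = NULL) {
  if (cutoff <= 0 || cutoff >= x$fs / 2)
    stop("cutoff must lie in (0, fs/2)")
  nt <- n_taps %||% default_taps(x$fs, n_samples(x), 401L)
  apply_fir_epochs(x, fir_highpass_kernel(x$fs, cutoff, nt))
}

#' @rdname highpass_filter
#' @export
lowpass_filter <- function(x, cutoff = 80, n_taps = NULL) {
  if (cutoff <= 0 || cutoff >= x$fs / 2)
    stop("cutoff must lie in (0, fs/2)")
  nt <- n_taps %||% default_taps(x$fs, n_samples(x), 501L)
  apply_fir_epochs(x, fir_lowpass_kernel(x$fs, cutoff, nt))
}
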