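# Epoched EEG container: channels x samples x trials, microvolts.

#' Construct an epoched EEG dataset
#'
#' @param data numeric array, channels x samples x trials, in microvolts.
#' @param fs sampling rate, samples/s.
#' @param t_start_ms time of the first sample relative to the TMS pulse
#'   (ms).  The time axis is `t_start_ms + (0:(samples-1)) * 1000 / fs`.
#' @param labels channel labels (unique, length = channels).
#' @param meta named list of provenance metadata (seed, generator config
#'   fingerprint, ...).
#' @return an object of class `epoched_data` with elements `data`, `fs`,
#'   `times` (ms), `labels`, `units` ("uV") and `meta`.
#' @export
epoched_data <- function(data, fs, t_start_ms, labels = NULL, meta = list()) {
  data <- as.array(data)
  if (length(dim(data)) != 3)
    stop("data must be a 3-d array (channels x samples x trials)")
  if (!all(is.finite(data))) stop("data must be finite")
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(data)[1]))
  if (length(labels) != dim(data)[1]) stop("labels/channel mismatch")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  times <- t_start_ms + (seq_len(dim(data)[2]) - 1) * 1000 / fs
  out <- list(data = data, fs = fs, times = times,
              labels = as.character(labels), units = "uV", meta = meta)
  class(out) <- "epoched_data"
  out
}

#' @export
print.epoched_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Epoched EEG: %d channels x %d samples x %d trials, fs = %g Hz, %g..%g ms\n",
    d[1], d[2], d[3], x$fs, x$times[1], x$times[length(x$times)]))
  invisible(x)
}

n_channels <- function(x) dim(x$data)[1]
n_samples <- function(x) dim(x$data)[2]
n_trials <- function(x) dim(x$data)[3]

# indices of samples with window[1] <= t <= window[2] (ms, closed interval)
time_window_idx <- function(x, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  idx <- which(x$times >= window[1] - 1e-9 & x$times <= window[2] + 1e-9)
  if (length(idx) == 0)
    stop("window [", window[1], ", ", window[2], "] ms contains no samples")
  idx
}

#' Baseline-correct epoched data
#'
#' Subtracts, per channel and trial, the mean over the baseline window.
#'
#' @param x an `epoched_data`.
#' @param window baseline window in ms (default -50 to -5, the pre-stimulus
#'   interval of the simulated epochs).
#' @return baseline-corrected `epoched_data`.
#' @export
baseline_correct <- function(x, window = c(-50, -5)) {
  idx <- time_window_idx(x, window)
  d <- dim(x$data)
  bl <- apply(x$data[, idx, , drop = FALSE], c(1, 3), mean)
  x$data <- x$data - aperm(array(bl, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  x
}

#' Global mean field amplitude of the trial-averaged response
#'
#' The spatial standard deviation across channels of the trial-averaged
#' potentials, one value per time point.
#'
#' @param x an `epoched_data` with at least two channels.
#' @return numeric vector, one value (uV) per time point.
#' @export
compute_gmfa <- function(x) {
  if (n_channels(x) < 2)
    stop("GMFA requires at least two channels")
  avg <- trial_average(x)
  cm <- colMeans(avg)
  sqrt(pmax(0, colMeans(avg^2) - cm^2))
}

# channels x samples trial average
trial_average <- function(x) {
  d <- dim(x$data)
  m <- x$data
  dim(m) <- c(d[1] * d[2], d[3])
  avg <- rowMeans(m)
  dim(avg) <- c(d[1], d[2])
  avg
}

#' Concatenate trials into a channels x (samples*trials) matrix
#'
#' Trial-major order: all samples of trial 1 first, then trial 2, etc.
#' The inverse mapping is [matrix_to_epochs()].
#'
#' @param x an `epoched_data`.
#' @return a channels x (samples*trials) matrix.
#' @export
concatenate_trials <- function(x) {
  d <- dim(x$data)
  m <- x$data
  dim(m) <- c(d[1], d[2] * d[3])
  m
}

#' @rdname concatenate_trials
#' @param mat a channels x (samples*trials) matrix.
#' @param like an `epoched_data` providing the shape and metadata.
#' @export
matrix_to_epochs <- function(mat, like) {
  d <- dim(like$data)
  stopifnot(nrow(mat) == d[1], ncol(mat) == d[2] * d[3])
  arr <- mat
  dim(arr) <- d
  out <- like
  out$data <- arr
  out
}
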