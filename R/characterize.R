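# Artifact characterization operators for measured (or measured-like) data:
# SVD artifact extraction, inter-trial coherence, minimum-norm montage
# extrapolation, TMS-pulse interval handling and signal-space angle
# distributions.

#' Extract the dominant artifact component by SVD
#'
#' SVD of the trials-concatenated data within the window (0-50 ms by
#' default); the first left singular vector is the muscle-artifact
#' topography and the per-trial time courses over the *full* epoch are its
#' projections `s_1k = u_1' Y_k`.  Sign convention: the largest-magnitude
#' element of the topography is positive.
#'
#' @param data an `epoched_data`.
#' @param window extraction window in ms.
#' @return list of class `artifact_profile_svd`: `topography` (unit norm),
#'   `trial_timecourses` (trials x samples), `singular_values`.
#' @export
extract_artifact_component <- function(data, window = c(0, 50)) {
  idx <- time_window_idx(data, window)
  m <- data$data[, idx, , drop = FALSE]
  dim(m) <- c(dim(m)[1], dim(m)[2] * dim(m)[3])
  sv <- svd(m, nu = 1, nv = 0)
  u1 <- sv$u[, 1]
  if (u1[which.max(abs(u1))] < 0) u1 <- -u1
  d <- dim(data$data)
  tc <- matrix(0, d[3], d[2])
  for (k in seq_len(d[3])) tc[k, ] <- as.numeric(u1 %*% data$data[, , k])
  list(topography = u1, trial_timecourses = tc,
       singular_values = sv$d, window = window)
}

# complex Morlet wavelet transform of signals-in-rows at one frequency
morlet_transform <- function(tc, fs, freq, n_cycles = 5) {
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(3.5 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sigma_t^2))
  w <- w / sqrt(sum(Mod(w)^2))
  ns <- ncol(tc)
  L <- length(w)
  nfft <- 2^ceiling(log2(ns + L - 1))
  W <- stats::fft(c(w, numeric(nfft - L)))
  X <- stats::mvfft(rbind(t(tc), matrix(0, nfft - ns, nrow(tc))))
  conv <- stats::mvfft(X * W, inverse = TRUE) / nfft
  # centered output (zero-phase alignment of the wavelet)
  t(conv[half + seq_len(ns), , drop = FALSE])
}

#' Inter-trial coherence (phase-locking factor)
#'
#' Morlet-wavelet phase per trial; ITC(f, t) is the modulus of the
#' trial-averaged unit phasor.  1 means perfect inter-trial phase
#' alignment (the opposite convention to the inter-trial variability index
#' alpha); the expected value for N independent uniform phases is
#' `sqrt(pi) / (2 sqrt(N))`.
#'
#' @param trial_timecourses trials x samples matrix (e.g. from
#'   [extract_artifact_component()]).
#' @param fs sampling rate (samples/s).
#' @param freqs analysis frequencies in Hz (default 20 log-spaced values
#'   from 10 Hz to 0.4 fs/2).
#' @param n_cycles Morlet width in cycles.
#' @return list of class `itc_result`: `itc` (freqs x times in \[0, 1\]),
#'   `freqs`, `n_trials`.
#' @export
itc <- function(trial_timecourses, fs, freqs = NULL, n_cycles = 5) {
  tc <- as.matrix(trial_timecourses)
  if (nrow(tc) < 2) stop("ITC requires at least two trials")
  freqs <- freqs %||% exp(seq(log(10), log(0.4 * fs), length.out = 20))
  if (any(freqs <= 0 | freqs >= fs / 2)) stop("freqs must lie in (0, fs/2)")
  out <- matrix(0, length(freqs), ncol(tc))
  for (fi in seq_along(freqs)) {
    Wt <- morlet_transform(tc, fs, freqs[fi], n_cycles)
    mag <- Mod(Wt)
    ph <- Wt / ifelse(mag > 0, mag, 1)
    out[fi, ] <- Mod(colMeans(ph))
  }
  res <- list(itc = out, freqs = freqs, n_trials = nrow(tc))
  class(res) <- "itc_result"
  res
}

#' Minimum-norm (MNE) montage extrapolation
#'
#' Tikhonov-regularized minimum-norm source estimate from a small montage,
#' re-projected through the full-montage lead field:
#' `X = L_s' (L_s L_s' + lambda I)^-1 Y`, `Y_full = L_f X`, with
#' `lambda = lambda_rel * trace(L_s L_s')`.  Both lead fields must come
#' from the same head model and source space.
#'
#' @param data_small `epoched_data` on the small montage.
#' @param leadfield_small,leadfield_full `leadfield` objects (or bare gain
#'   matrices) sharing the source space.
#' @param lambda_rel relative regularization (default 1e-5).
#' @return `epoched_data` on the full montage.
#' @export
mne_extrapolate <- function(data_small, leadfield_small, leadfield_full,
                            lambda_rel = 1e-5) {
  Ls <- if (inherits(leadfield_small, "leadfield")) leadfield_small$gain
  else leadfield_small
  Lf <- if (inherits(leadfield_full, "leadfield")) leadfield_full$gain
  else leadfield_full
  if (lambda_rel <= 0) stop("lambda_rel must be positive")
  if (nrow(Ls) != n_channels(data_small))
    stop("small lead field does not match the data channels")
  if (ncol(Ls) != ncol(Lf))
    stop("lead fields must share the source space")
  G <- tcrossprod(Ls)
  lambda <- lambda_rel * sum(diag(G))
  Op <- Lf %*% t(Ls) %*% solve(G + lambda * diag(nrow(G)))
  m <- Op %*% concatenate_trials(data_small)
  labels_full <- if (inherits(leadfield_full, "leadfield"))
    leadfield_full$montage$label else paste0("ch", seq_len(nrow(Lf)))
  epoched_data(array(m, dim = c(nrow(Lf), n_samples(data_small),
                                n_trials(data_small))),
               data_small$fs, data_small$times[1], labels_full,
               meta = c(data_small$meta,
                        list(extrapolated = TRUE, lambda_rel = lambda_rel)))
}

#' Zero or interpolate the TMS-pulse interval
#'
#' `zero_pulse_interval` replaces all samples with `interval[1] <= t <=
#' interval[2]` by exact zeros.  `interpolate_interval` replaces them by
#' shape-preserving piecewise-cubic (Fritsch-Carlson monotone) interpolation
#' through the samples bordering the interval, per channel and trial.
#'
#' @param data an `epoched_data`.
#' @param interval time interval in ms (default -1 to 5).
#' @param n_anchor number of boundary samples on each side used as
#'   interpolation knots.
#' @return modified `epoched_data`.
#' @export
zero_pulse_interval <- function(data, interval = c(-1, 5)) {
  idx <- time_window_idx(data, interval)
  data$data[, idx, ] <- 0
  data
}

#' @rdname zero_pulse_interval
#' @export
interpolate_interval <- function(data, interval = c(-1, 5), n_anchor = 8) {
  idx <- time_window_idx(data, interval)
  ns <- n_samples(data)
  if (idx[1] <= 1 || idx[length(idx)] >= ns)
    stop("interval touches the epoch edge: no boundary samples to anchor",
         " the interpolation")
  lo <- max(1, idx[1] - n_anchor)
  hi <- min(ns, idx[length(idx)] + n_anchor)
  anchors <- setdiff(lo:hi, idx)
  tx <- data$times[anchors]
  d <- dim(data$data)
  for (tr in seq_len(d[3])) {
    for (ch in seq_len(d[1])) {
      f <- stats::splinefun(tx, data$data[ch, anchors, tr],
                            method = "monoH.FC")
      data$data[ch, idx, tr] <- f(data$times[idx])
    }
  }
  data
}

#' Signal-space angle distribution between a topography and all patterns
#'
#' Angles (degrees, 0-180) between a unit-norm artifact topography and the
#' potential pattern at every trial and time point of the window, with
#' summary statistics for violin-style reporting.  Zero-norm patterns are
#' excluded and counted.
#'
#' @param topography unit-norm channel vector.
#' @param data an `epoched_data`.
#' @param window time window in ms.
#' @return list of class `angle_distribution`: `angles_deg` (trials x time
#'   matrix, NA where excluded), `median`, `mean`, `whiskers` (2.5% and
#'   97.5% quantiles), `n_excluded`.
#' @export
angle_distribution <- function(topography, data, window = c(0, 100)) {
  if (abs(vnorm(topography) - 1) > 1e-6)
    stop("topography must be unit norm")
  idx <- time_window_idx(data, window)
  d <- dim(data$data)
  ang <- matrix(NA_real_, d[3], length(idx))
  excluded <- 0L
  for (tr in seq_len(d[3])) {
    m <- data$data[, idx, tr, drop = TRUE]
    nrm <- sqrt(colSums(m^2))
    ok <- nrm > .Machine$double.eps
    excluded <- excluded + sum(!ok)
    cosv <- as.numeric(crossprod(m[, ok, drop = FALSE], topography)) /
      nrm[ok]
    ang[tr, ok] <- acos(pmax(-1, pmin(1, cosv))) * 180 / pi
  }
  v <- ang[!is.na(ang)]
  out <- list(angles_deg = ang,
              median = stats::median(v), mean = mean(v),
              whiskers = stats::quantile(v, c(0.025, 0.975), names = FALSE),
              n_excluded = excluded, window = window)
  class(out) <- "angle_distribution"
  out
}

#' Characterize the artifact content of an epoched dataset
#'
#' Convenience wrapper reproducing the real-world characterization chain on
#' any epoched dataset: SVD artifact extraction in the 0-50 ms window, ITC
#' of the extracted trial time courses, and the angle distribution between
#' the extracted topography and reference (e.g. artifact-free) data.
#'
#' @param data artifactual `epoched_data`.
#' @param reference_data clean data for the angle analysis (defaults to
#'   `data` itself).
#' @param window extraction window (ms).
#' @param angle_window angle-analysis window (ms).
#' @param freqs ITC frequencies.
#' @return list of class `artifact_profile`: `topography`,
#'   `trial_timecourses`, `itc` (an `itc_result`), `angles` (an
#'   `angle_distribution`).
#' @export
characterize_artifact <- function(data, reference_data = NULL,
                                  window = c(0, 50),
                                  angle_window = c(0, 100), freqs = NULL) {
  comp <- extract_artifact_component(data, window)
  profile <- list(
    topography = comp$topography,
    trial_timecourses = comp$trial_timecourses,
    itc = itc(comp$trial_timecourses, data$fs, freqs),
    angles = angle_distribution(comp$topography, reference_data %||% data,
                                angle_window))
  class(profile) <- "artifact_profile"
  profile
}
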