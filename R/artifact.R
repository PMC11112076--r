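# Simulated TMS-evoked scalp-muscle artifacts.
#
# Trial time courses follow
#   a_i(t) = (1 - alpha) * phi_s(t) + alpha * S_i * phi_s(t - phi_i),
# where phi_s is a Daubechies order-4 wavelet (dyadic scale 4) whose support
# is mapped onto the first 20 ms of the epoch, S_i is a random sign and
# phi_i a random translation uniform on [0, 10] ms.  alpha = 0 gives perfect
# inter-trial consistency; alpha = 1 fully randomized phase.  Topographies
# are lead-field columns of superficial right-lateral tangential dipoles in
# a head model with variable skull conductivity contrast and tangentially
# jittered electrodes (a different model than the one used inside SSP-SIR).

db4_scaling_coefs <- c(
  0.230377813308855230, 0.714846570552541500, 0.630880767929590400,
  -0.027983769416983850, -0.187034811718881140, 0.030841381835986965,
  0.032883011666982945, -0.010597401784997278)

# continuous Daubechies-4 wavelet function psi on its natural support [0, 7],
# built by the cascade algorithm at dyadic resolution 2^-levels
db4_wavelet_fine <- function(levels = 10) {
  key <- paste0("db4_fine_", levels)
  if (!is.null(.tmseegsim_cache[[key]])) return(.tmseegsim_cache[[key]])
  h <- db4_scaling_coefs
  g <- rev(h) * (-1)^(seq_along(h) - 1) # QMF wavelet filter
  upsample2 <- function(v) {
    out <- numeric(2 * length(v) - 1)
    out[seq(1, length(out), by = 2)] <- v
    out
  }
  lin_conv <- function(a, b) stats::convolve(a, rev(b), type = "open")
  # inverse cascade: one detail coefficient reconstructed through `levels`
  # synthesis stages (first with the wavelet filter, then scaling filters)
  v <- g
  for (j in seq_len(levels - 1)) v <- lin_conv(upsample2(v), h)
  tt <- seq(0, 7, length.out = length(v))
  out <- list(t = tt, psi = v / max(abs(v)))
  .tmseegsim_cache[[key]] <- out
  out
}

# evaluate the unit-peak prototype at arbitrary times (ms); exact zero
# outside [0, support_ms]
wavelet_eval <- function(t_ms, support_ms = 20) {
  fine <- db4_wavelet_fine()
  out <- numeric(length(t_ms))
  inside <- t_ms >= 0 & t_ms <= support_ms
  if (any(inside))
    out[inside] <- stats::approx(fine$t, fine$psi,
                                 xout = t_ms[inside] / support_ms * 7,
                                 rule = 2)$y
  out
}

#' Daubechies-4 artifact prototype sampled on the epoch grid
#'
#' The wavelet function of the Daubechies order-4 family at dyadic scale 4,
#' generated with the cascade algorithm, onset-aligned with the TMS pulse
#' (t = 0), compressed so its whole support spans the first 20 ms, unit
#' peak amplitude and exactly zero outside the support.  Its sharp time
#' course gives the broadband spectrum that the SSP-SIR high-pass step
#' relies on.
#'
#' @param fs sampling rate (samples/s).
#' @param t_start_ms,t_end_ms epoch limits (ms).
#' @param support_ms wavelet support (default 20 ms, within which real
#'   TMS-evoked muscle artifacts peak).
#' @return numeric vector phi_s(t) on the epoch grid, with the time axis in
#'   attribute `"times"`.
#' @export
wavelet_prototype <- function(fs = 5000, t_start_ms = -50, t_end_ms = 150,
                              support_ms = 20) {
  nsamp <- as.integer(round((t_end_ms - t_start_ms) * fs / 1000))
  times <- t_start_ms + (seq_len(nsamp) - 1) * 1000 / fs
  phi <- wavelet_eval(times, support_ms)
  attr(phi, "times") <- times
  phi
}

# per-trial random signs and translations (uniform on [0, shift_max_ms])
artifact_trial_params <- function(n_trials, seed, shift_max_ms = 10) {
  with_seed(seed, {
    signs <- sample(c(-1, 1), n_trials, replace = TRUE)
    shifts <- stats::runif(n_trials, 0, shift_max_ms)
    list(signs = signs, shifts_ms = shifts)
  })
}

#' Simulate artifact trial time courses
#'
#' Implements the inter-trial variability model
#' `a_i(t) = (1 - alpha) phi_s(t) + alpha S_i phi_s(t - phi_i)`.
#' Translations are continuous (the prototype is evaluated as a continuous
#' function at shifted time points), so the artifact support is exactly
#' `[0, support + max shift]` ms.
#'
#' @param alpha inter-trial variability index in \[0, 1\]: 0 = identical
#'   trials, 1 = fully randomized sign and translation.
#' @param n_trials number of trials.
#' @param seed RNG seed for the per-trial signs and shifts.
#' @param fs,t_start_ms,t_end_ms epoch grid.
#' @param shift_max_ms maximal random translation (default 10 ms).
#' @return trials x samples matrix with attributes `signs`, `shifts_ms`,
#'   `times`.
#' @export
simulate_timecourses <- function(alpha, n_trials, seed = 1L, fs = 5000,
                                 t_start_ms = -50, t_end_ms = 150,
                                 shift_max_ms = 10) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  pars <- artifact_trial_params(n_trials, seed, shift_max_ms)
  nsamp <- as.integer(round((t_end_ms - t_start_ms) * fs / 1000))
  times <- t_start_ms + (seq_len(nsamp) - 1) * 1000 / fs
  base <- wavelet_eval(times)
  tc <- matrix(0, n_trials, nsamp)
  for (i in seq_len(n_trials)) {
    tc[i, ] <- (1 - alpha) * base +
      alpha * pars$signs[i] * wavelet_eval(times - pars$shifts_ms[i])
  }
  attr(tc, "signs") <- pars$signs
  attr(tc, "shifts_ms") <- pars$shifts_ms
  attr(tc, "times") <- times
  tc
}

#' The 11-value skull-to-skin/brain conductivity contrast grid
#' @return numeric vector of length 11: 1, 1/20, 1/40, ..., 1/200.
#' @export
default_contrasts <- function() c(1, 1 / (20 * (1:10)))

#' The 121-condition artifact grid
#'
#' All combinations of the 11 inter-trial variability values (0 to 1 in
#' steps of 0.1) and the 11 skull conductivity contrasts, at one artifact
#' amplitude.
#'
#' @param alphas inter-trial variability grid.
#' @param contrasts conductivity-contrast grid.
#' @param amplitude_uv target maximum peak-to-peak amplitude (uV).
#' @return data.frame with columns `alpha`, `contrast`, `amplitude_uv`.
#' @export
artifact_conditions <- function(alphas = seq(0, 1, by = 0.1),
                                contrasts = default_contrasts(),
                                amplitude_uv = 250) {
  out <- expand.grid(alpha = alphas, contrast = contrasts,
                     KEEP.OUT.ATTRS = FALSE)
  out$amplitude_uv <- amplitude_uv
  out
}

# cached artifact-model lead field columns for one contrast:
# 60 x 9 matrix of average-referenced topographies from the perturbed montage
artifact_gain <- function(contrast, montage = NULL, sources = NULL,
                          series_terms = 80) {
  key <- sprintf("art_gain_%.10g_%d_%s", contrast, series_terms,
                 if (is.null(montage)) "default" else
                   config_fingerprint(montage))
  if (is.null(montage) && is.null(sources) &&
      !is.null(.tmseegsim_cache[[key]]))
    return(.tmseegsim_cache[[key]])
  mnt <- montage %||% perturb_montage(build_montage_1020(60))
  src <- sources %||% sample_artifact_sources()
  G <- compute_leadfield(artifact_head_model(contrast, series_terms),
                         src, mnt, average_reference = TRUE)$gain
  if (is.null(montage) && is.null(sources)) .tmseegsim_cache[[key]] <- G
  G
}

#' Simulated muscle-artifact topography
#'
#' Lead-field column of one of the nine right-lateral tangential artifact
#' dipoles, computed in the artifact head model at the requested skull
#' conductivity contrast with tangentially jittered electrode positions,
#' average-referenced and normalized to unit norm.
#'
#' @param contrast skull-to-skin/brain conductivity contrast, one of
#'   [default_contrasts()].
#' @param source_index which of the 9 artifact sources (1-based).
#' @param montage optional alternative montage (default: jittered
#'   60-channel theoretical montage).
#' @param sources optional alternative [source_space()].
#' @return unit-norm channel vector.
#' @export
make_topography <- function(contrast, source_index, montage = NULL,
                            sources = NULL) {
  if (!any(abs(contrast - default_contrasts()) < 1e-12))
    stop("contrast must be one of the 11 declared values")
  if (!is_count(source_index) || source_index > 9)
    stop("source_index must be in 1..9")
  G <- artifact_gain(contrast, montage, sources)
  unit(G[, source_index])
}

#' Scale an artifact to a target maximum peak-to-peak amplitude
#'
#' The scale is chosen so that the maximum over channels and trials of the
#' peak-to-peak (max minus min over time) amplitude of
#' `topography %o% timecourses` equals `target_uv` exactly.
#'
#' @param topography unit-norm channel vector.
#' @param timecourses trials x samples matrix from [simulate_timecourses()].
#' @param target_uv target maximum peak-to-peak amplitude (uV).
#' @return an object of class `artifact_realization`: list with
#'   `topography` (unit norm), `timecourses` (trials x samples, uV, already
#'   scaled), `signs`, `shifts_ms`, `scale`, `target_uv`.
#' @export
scale_to_p2p <- function(topography, timecourses, target_uv = 250) {
  if (max(abs(topography)) == 0 || max(abs(timecourses)) == 0)
    stop("cannot scale an all-zero artifact")
  stopifnot(target_uv > 0)
  # rank-1 per trial: p2p(channel c, trial i) = |topo_c| * range(a_i)
  ranges <- apply(timecourses, 1, function(v) max(v) - min(v))
  cur <- max(abs(topography)) * max(ranges)
  sc <- target_uv / cur
  out <- list(topography = as.numeric(topography),
              timecourses = timecourses * sc,
              signs = attr(timecourses, "signs"),
              shifts_ms = attr(timecourses, "shifts_ms"),
              times = attr(timecourses, "times"),
              scale = sc, target_uv = target_uv)
  class(out) <- "artifact_realization"
  out
}

#' Simulate one artifact realization for a grid condition
#'
#' Convenience wrapper: draws the trial time courses for `alpha`, picks the
#' topography for (`contrast`, `source_index`) and scales to the target
#' peak-to-peak amplitude.
#'
#' @param alpha,contrast,amplitude_uv the artifact condition.
#' @param source_index artifact source (1..9).
#' @param n_trials,fs,t_start_ms,t_end_ms epoch geometry.
#' @param seed RNG seed.
#' @return an `artifact_realization`.
#' @export
simulate_artifact <- function(alpha, contrast, amplitude_uv = 250,
                              source_index = 1, n_trials = 173, fs = 5000,
                              t_start_ms = -50, t_end_ms = 150, seed = 1L) {
  tc <- simulate_timecourses(alpha, n_trials, seed, fs, t_start_ms, t_end_ms)
  topo <- make_topography(contrast, source_index)
  r <- scale_to_p2p(topo, tc, amplitude_uv)
  r$condition <- list(alpha = alpha, contrast = contrast,
                      amplitude_uv = amplitude_uv,
                      source_index = source_index, seed = seed)
  r
}

# channels x samples x trials tensor of a realization
artifact_tensor <- function(realization) {
  tc <- realization$timecourses # trials x samples
  nch <- length(realization$topography)
  out <- outer(realization$topography, t(tc)) # ch x samples x trials
  dim(out) <- c(nch, ncol(tc), nrow(tc))
  out
}

#' Superpose an artifact realization on a ground-truth dataset
#'
#' @param ground_truth an `epoched_data`.
#' @param artifact an `artifact_realization` with matching geometry.
#' @return `epoched_data` with the artifact added; provenance in `meta`.
#' @export
superpose <- function(ground_truth, artifact) {
  d <- dim(ground_truth$data)
  tc <- artifact$timecourses
  if (length(artifact$topography) != d[1] || ncol(tc) != d[2] ||
      nrow(tc) != d[3])
    stop("artifact and data shapes do not match")
  out <- ground_truth
  out$data <- ground_truth$data + artifact_tensor(artifact)
  out$meta$artifact <- artifact$condition %||%
    list(scale = artifact$scale, target_uv = artifact$target_uv)
  out
}

#' Signal-space angle between two channel vectors
#'
#' `acos` of the normalized inner product, in degrees on \[0, 180\] (no
#' absolute value: anti-correlated patterns map to angles above 90).
#'
#' @param u,v channel vectors.
#' @return angle in degrees.
#' @export
signal_space_angle <- function(u, v) {
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu == 0 || nv == 0) stop("angle undefined for a zero vector")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Angle profile between an artifact topography and evoked data
#'
#' Angles between a unit-norm artifact topography and the trial-averaged
#' potential pattern at every time point of the window, plus the 5th
#' percentile over time (the "minimum angle" summary).  Time points with a
#' zero-norm data vector are excluded with a warning.
#'
#' @param topography unit-norm channel vector.
#' @param data an `epoched_data`.
#' @param window time window in ms (default 0 to 100).
#' @return list with `times`, `angles_deg`, `p5_deg`.
#' @export
topography_angle_profile <- function(topography, data, window = c(0, 100)) {
  if (abs(vnorm(topography) - 1) > 1e-6)
    stop("topography must be unit norm")
  idx <- time_window_idx(data, window)
  avg <- trial_average(data)[, idx, drop = FALSE]
  nrm <- sqrt(colSums(avg^2))
  ok <- nrm > .Machine$double.eps
  if (!all(ok))
    warning(sum(!ok), " time points with zero-norm patterns excluded")
  cosv <- as.numeric(crossprod(avg[, ok, drop = FALSE], topography)) / nrm[ok]
  ang <- acos(pmax(-1, pmin(1, cosv))) * 180 / pi
  list(times = data$times[idx][ok], angles_deg = ang,
       p5_deg = as.numeric(stats::quantile(ang, 0.05)))
}

#' Median minimum angle across the nine artifact sources
#'
#' For one conductivity contrast: the median over the 9 artifact
#' topographies of the 5th-percentile angle between each topography and the
#' trial-averaged ground-truth patterns in the first 100 ms.
#'
#' @param contrast skull conductivity contrast.
#' @param data ground-truth `epoched_data`.
#' @param window time window (ms).
#' @return median minimum angle in degrees.
#' @export
angle_summary_for_contrast <- function(contrast, data, window = c(0, 100)) {
  p5 <- vapply(1:9, function(i) {
    topography_angle_profile(make_topography(contrast, i), data,
                             window)$p5_deg
  }, numeric(1))
  stats::median(p5)
}
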