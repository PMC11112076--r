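# Synthetic ground-truth TMS-evoked potentials.
#
# The generator emulates the statistical structure of a carefully
# preprocessed single-subject TEP dataset: a small number of Gaussian-
# windowed sinusoidal source deflections (right motor region and midline)
# with per-trial amplitude and latency jitter, 1/f ongoing background
# activity projected through the same lead field, white sensor noise to
# guarantee full channel rank, an 80-Hz zero-phase low-pass, per-trial
# baseline correction, and a final global calibration so the maximum GMFA
# of the trial-averaged response equals the target (1.5 uV by default).

# fixed neuronal source geometry: 6 dipoles, right motor region + midline
gt_source_geometry <- function(n_sources, brain_radius_mm = 80,
                               depth_frac = 0.85) {
  dirs <- rbind(
    c(0.55, 0.25, 0.80),   # right M1
    c(0.45, 0.45, 0.77),   # right premotor
    c(0.05, 0.10, 0.99),   # midline central
    c(0.00, 0.55, 0.83),   # midline frontal
    c(0.45, -0.35, 0.82),  # right parietal
    c(-0.35, 0.15, 0.92))  # left central
  if (n_sources > nrow(dirs))
    stop("at most ", nrow(dirs), " ground-truth sources are supported")
  dirs <- dirs[seq_len(n_sources), , drop = FALSE]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  P <- dirs * brain_radius_mm * depth_frac
  O <- matrix(0, n_sources, 3)
  for (i in seq_len(n_sources)) {
    d <- dirs[i, ]
    ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    t1 <- unit(ref - sum(ref * d) * d)
    t2 <- c(d[2] * t1[3] - d[3] * t1[2],
            d[3] * t1[1] - d[1] * t1[3],
            d[1] * t1[2] - d[2] * t1[1])
    psi <- (i - 1) * 2.399963 # golden-angle spread of tangential directions
    O[i, ] <- cos(psi) * t1 + sin(psi) * t2
  }
  source_space(P, O)
}

#' Configuration of the synthetic ground-truth dataset
#'
#' Defaults reproduce the geometry of the emulated recording: 60 channels,
#' 173 trials, 1,000 samples from -50 to 150 ms at 5,000 Hz, content
#' low-passed at 80 Hz, trial-averaged GMFA maximum calibrated to 1.5 uV.
#'
#' @param n_channels number of channels (60; must match the montage).
#' @param n_trials number of trials (173).
#' @param t_start_ms,t_end_ms epoch limits in ms relative to the TMS pulse.
#' @param fs sampling rate, samples/s.
#' @param peak_latencies_ms,peak_freqs_hz,peak_widths_ms,peak_amps_rel
#'   per-source deflection atoms: Gaussian-windowed sinusoids with these
#'   latencies, carrier frequencies, Gaussian SDs and relative amplitudes.
#'   The number of sources is the common length of these vectors (max 6).
#' @param amp_jitter_sd per-trial log-normal amplitude jitter SD.
#' @param latency_jitter_sd_ms per-trial Gaussian latency jitter SD (ms).
#' @param bg_rms_uv channel RMS of the 1/f ongoing background activity
#'   (before final calibration).
#' @param noise_rms_uv sensor white-noise RMS (guarantees full channel rank
#'   for ICA; before final calibration).
#' @param n_bg_sources number of background dipoles.
#' @param lowpass_hz low-pass cutoff (< fs/2).
#' @param gmfa_target_uv calibration target for the maximum of the
#'   trial-averaged GMFA.
#' @param seed RNG seed; the dataset is a deterministic function of the
#'   configuration.
#' @return a list of class `ground_truth_config`.
#' @export
ground_truth_config <- function(n_channels = 60, n_trials = 173,
                                t_start_ms = -50, t_end_ms = 150, fs = 5000,
                                peak_latencies_ms = c(15, 30, 45, 60, 100, 180),
                                peak_freqs_hz = c(30, 22, 18, 12, 10, 8),
                                peak_widths_ms = c(5, 7, 10, 12, 20, 30),
                                peak_amps_rel = c(1, 0.8, 0.9, 0.7, 0.6, 0.5),
                                amp_jitter_sd = 0.2,
                                latency_jitter_sd_ms = 2,
                                bg_rms_uv = 4, noise_rms_uv = 1,
                                n_bg_sources = 20,
                                lowpass_hz = 80, gmfa_target_uv = 1.5,
                                seed = 1L) {
  cfg <- list(n_channels = n_channels, n_trials = n_trials,
              t_start_ms = t_start_ms, t_end_ms = t_end_ms, fs = fs,
              peak_latencies_ms = peak_latencies_ms,
              peak_freqs_hz = peak_freqs_hz,
              peak_widths_ms = peak_widths_ms,
              peak_amps_rel = peak_amps_rel,
              amp_jitter_sd = amp_jitter_sd,
              latency_jitter_sd_ms = latency_jitter_sd_ms,
              bg_rms_uv = bg_rms_uv, noise_rms_uv = noise_rms_uv,
              n_bg_sources = n_bg_sources, lowpass_hz = lowpass_hz,
              gmfa_target_uv = gmfa_target_uv, seed = as.integer(seed))
  validate_gt_config(cfg)
  class(cfg) <- "ground_truth_config"
  cfg
}

validate_gt_config <- function(cfg) {
  ns <- length(cfg$peak_latencies_ms)
  if (!all(lengths(cfg[c("peak_freqs_hz", "peak_widths_ms",
                         "peak_amps_rel")]) == ns))
    stop("peak_* vectors must have a common length")
  if (!(cfg$t_start_ms < 0 && 0 < cfg$t_end_ms))
    stop("epoch must straddle the pulse: t_start < 0 < t_end")
  if (!(cfg$lowpass_hz < cfg$fs / 2)) stop("lowpass_hz must be < fs/2")
  with(cfg, stopifnot(
    is_count(n_channels), is_count(n_trials), fs > 0,
    all(peak_freqs_hz > 0), all(peak_widths_ms > 0),
    all(peak_amps_rel > 0), amp_jitter_sd >= 0, latency_jitter_sd_ms >= 0,
    bg_rms_uv >= 0, noise_rms_uv >= 0, is_count(n_bg_sources),
    gmfa_target_uv > 0))
  invisible(cfg)
}

gt_n_samples <- function(cfg)
  as.integer(round((cfg$t_end_ms - cfg$t_start_ms) * cfg$fs / 1000))

# 1/f amplitude-spectrum noise, one column per signal
one_over_f_noise <- function(ns, ncol, fs) {
  w <- matrix(stats::rnorm(ns * ncol), ns, ncol)
  W <- stats::mvfft(w)
  k <- 0:(ns - 1)
  f <- pmin(k, ns - k) * fs / ns # symmetric FFT frequency magnitudes
  shape <- 1 / sqrt(pmax(f, 1))  # flat below 1 Hz, 1/f amplitude above
  shape[1] <- 0                 # no DC
  out <- Re(stats::mvfft(W * shape, inverse = TRUE)) / ns
  out / sqrt(mean(out^2))
}

#' Generate the synthetic ground-truth TEP dataset
#'
#' @param config a [ground_truth_config()].
#' @param montage the electrode montage (default: 60-channel theoretical
#'   10-20 montage).  Must match `config$n_channels`.
#' @param model head model used to project sources (default: reference
#'   three-layer model, the same instance SIR uses).
#' @return an `epoched_data`, average-referenced, baseline-corrected,
#'   low-passed and GMFA-calibrated; fully reproducible from the config.
#' @export
generate_ground_truth <- function(config = ground_truth_config(),
                                  montage = NULL, model = NULL) {
  validate_gt_config(config)
  montage <- montage %||% build_montage_1020(60)
  if (nrow(montage) != config$n_channels)
    stop("montage size does not match n_channels")
  model <- model %||% spherical_head_model()
  nsamp <- gt_n_samples(config)
  times <- config$t_start_ms + (seq_len(nsamp) - 1) * 1000 / config$fs
  nsrc <- length(config$peak_latencies_ms)
  ntr <- config$n_trials

  sspace <- gt_source_geometry(nsrc, model$radii_mm[1])
  L <- compute_leadfield(model, sspace, montage)$gain

  with_seed(config$seed, {
    # --- deterministic-atom signal with per-trial jitter ------------------
    sig <- array(0, dim = c(config$n_channels, nsamp, ntr))
    lat_jit <- matrix(stats::rnorm(nsrc * ntr, 0, config$latency_jitter_sd_ms),
                      nsrc, ntr)
    amp_jit <- matrix(exp(stats::rnorm(nsrc * ntr, 0, config$amp_jitter_sd)),
                      nsrc, ntr)
    for (i in seq_len(ntr)) {
      X <- matrix(0, nsrc, nsamp)
      for (s in seq_len(nsrc)) {
        lat <- config$peak_latencies_ms[s] + lat_jit[s, i]
        w <- config$peak_widths_ms[s]
        f <- config$peak_freqs_hz[s]
        # cosine carrier: the deflection extremum sits at the configured
        # latency (the Gaussian envelope peak)
        X[s, ] <- config$peak_amps_rel[s] * amp_jit[s, i] *
          exp(-(times - lat)^2 / (2 * w^2)) *
          cos(2 * pi * f * (times - lat) / 1000)
      }
      sig[, , i] <- L %*% X
    }
    # scale the signal part so its trial-averaged GMFA peaks at the target
    sig_ep <- epoched_data(sig, config$fs, config$t_start_ms, montage$label)
    sig <- sig * (config$gmfa_target_uv / max(compute_gmfa(sig_ep)))

    # --- 1/f background through the lead field ----------------------------
    bg_dirs <- matrix(stats::rnorm(config$n_bg_sources * 3),
                      config$n_bg_sources, 3)
    bg_dirs <- bg_dirs / sqrt(rowSums(bg_dirs^2))
    bg_pos <- bg_dirs * model$radii_mm[1] *
      stats::runif(config$n_bg_sources, 0.4, 0.85)
    bg_ori <- matrix(stats::rnorm(config$n_bg_sources * 3),
                     config$n_bg_sources, 3)
    bg_ori <- bg_ori / sqrt(rowSums(bg_ori^2))
    Lbg <- compute_leadfield(model, source_space(bg_pos, bg_ori),
                             montage)$gain
    bg <- array(0, dim = c(config$n_channels, nsamp, ntr))
    for (i in seq_len(ntr)) {
      bg[, , i] <- Lbg %*% t(one_over_f_noise(nsamp, config$n_bg_sources,
                                              config$fs))
    }
    bg <- bg * (config$bg_rms_uv / sqrt(mean(bg^2)))

    # --- white sensor noise ----------------------------------------------
    noise <- array(stats::rnorm(length(sig), 0, config$noise_rms_uv),
                   dim = dim(sig))

    x <- epoched_data(sig + bg + noise, config$fs, config$t_start_ms,
                      montage$label,
                      meta = list(seed = config$seed,
                                  config = config_fingerprint(config),
                                  generator = "generate_ground_truth"))
  })
  x <- lowpass_filter(x, config$lowpass_hz)
  # average reference (lead-field columns already are; noise is not)
  x$data <- sweep(x$data, c(2, 3), colMeans(x$data))
  x <- baseline_correct(x, c(config$t_start_ms, -5))
  # final exact calibration of the trial-averaged GMFA maximum
  x$data <- x$data * (config$gmfa_target_uv / max(compute_gmfa(x)))
  x
}
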