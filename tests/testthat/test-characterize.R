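test_that("SVD artifact extraction on a rank-1 dataset", {
  fs <- 1000
  tc <- simulate_timecourses(0.3, 12, seed = 6, fs = fs)
  topo <- make_topography(1 / 40, 4)
  r <- scale_to_p2p(topo, tc, 120)
  x <- epoched_data(tmseegsim:::artifact_tensor(r), fs, -50)
  comp <- extract_artifact_component(x)
  expect_gt(abs(sum(comp$topography * topo)), 0.999)
  # sign convention: largest-magnitude element positive
  expect_gt(comp$topography[which.max(abs(comp$topography))], 0)
  # per-trial time courses recover the generators up to a common scale
  for (i in c(1, 5, 12))
    expect_gt(abs(stats::cor(comp$trial_timecourses[i, ],
                             r$timecourses[i, ])), 0.999)
  expect_error(extract_artifact_component(x, c(900, 950)), "no samples")
})

test_that("inter-trial coherence: locked, random, and scale-invariant", {
  fs <- 1000
  # identical trials: ITC = 1 wherever there is power
  base <- as.numeric(wavelet_prototype(fs = fs)) +
    0.3 * sin(2 * pi * 40 * (0:199) / fs)
  tc_locked <- matrix(rep(base, 20), 20, byrow = TRUE)
  r1 <- itc(tc_locked, fs)
  expect_true(all(r1$itc > 0.9999))
  expect_true(all(r1$itc <= 1 + 1e-12))
  # independent noise trials: mean ITC near sqrt(pi)/(2 sqrt(N))
  set.seed(9)
  tc_rand <- matrix(stats::rnorm(173 * 300), 173, 300)
  r2 <- itc(tc_rand, fs)
  center <- r2$itc[, 50:250]
  expect_gt(mean(center), 0.05)
  expect_lt(mean(center), 0.085) # E[R] = 0.0674 for N = 173
  # phase-only statistic: invariant to common scaling
  r3 <- itc(2.5 * tc_rand, fs)
  expect_equal(r3$itc, r2$itc, tolerance = 1e-12)
  expect_error(itc(tc_rand[1, , drop = FALSE], fs), "two trials")
  expect_error(itc(tc_rand, fs, freqs = c(10, 600)), "fs/2")
})

test_that("MNE extrapolation", {
  model <- spherical_head_model()
  sspace <- sir_source_space()
  m60 <- build_montage_1020(60)
  m30 <- build_montage_1020(30)
  lf60 <- compute_leadfield(model, sspace, m60)
  lf30 <- compute_leadfield(model, sspace, m30)
  # lead-field-generated pattern on both montages
  set.seed(23)
  X <- matrix(stats::rnorm(ncol(lf60$gain) * 40), ncol(lf60$gain), 40)
  y60 <- epoched_data(array(lf60$gain %*% X, dim = c(60, 20, 2)), 1000, -5)
  y30 <- epoched_data(array(lf30$gain %*% X, dim = c(30, 20, 2)), 1000, -5,
                      labels = m30$label)
  # identity montage: near-interpolation limit
  same <- mne_extrapolate(y60, lf60, lf60)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(same$data - y60$data) / rms(y60$data), 0.01)
  # 30 -> 60 extrapolation recovers the full-montage pattern
  up <- mne_extrapolate(y30, lf30, lf60)
  for (k in c(1, 10, 20)) {
    a <- up$data[, k, 1]
    b <- y60$data[, k, 1]
    expect_gt(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 0.98)
  }
  # infinite regularization drives the output to zero
  dead <- mne_extrapolate(y30, lf30, lf60, lambda_rel = 1e12)
  expect_lt(rms(dead$data) / rms(y60$data), 1e-6)
  expect_error(mne_extrapolate(y30, lf60, lf60), "channels")
  expect_error(mne_extrapolate(y30, lf30, lf30$gain[, 1:10]),
               "source space")
  expect_error(mne_extrapolate(y30, lf30, lf60, lambda_rel = 0),
               "positive")
})

test_that("pulse-interval zeroing and shape-preserving interpolation", {
  gt <- gt_small()
  z <- zero_pulse_interval(gt)
  idx <- which(gt$times >= -1 & gt$times <= 5)
  expect_true(all(z$data[, idx, ] == 0))
  expect_identical(z$data[, -idx, ], gt$data[, -idx, ])
  # interpolating a linear signal reproduces it exactly
  lin <- epoched_data(array(rep(seq(-2, 2, length.out = 100), 2),
                            dim = c(1, 100, 2)), 1000, -50)
  li <- interpolate_interval(lin)
  expect_equal(li$data, lin$data, tolerance = 1e-12)
  # no new extrema beyond the anchor values (random smooth signals)
  set.seed(3)
  fs <- 1000
  t <- (0:199) / fs
  for (k in 1:5) {
    sig <- as.numeric(stats::filter(stats::rnorm(200), rep(0.2, 5),
                                    circular = TRUE))
    x <- epoched_data(array(sig, dim = c(1, 200, 1)), fs, -50)
    xi <- interpolate_interval(x, c(-1, 5))
    ii <- which(x$times >= -1 & x$times <= 5)
    anchors <- setdiff(max(1, ii[1] - 8):min(200, ii[length(ii)] + 8), ii)
    expect_true(all(xi$data[1, ii, 1] <= max(sig[anchors]) + 1e-12))
    expect_true(all(xi$data[1, ii, 1] >= min(sig[anchors]) - 1e-12))
  }
  # interval at the epoch edge: no anchor on one side
  expect_error(interpolate_interval(gt, c(-50, 0)), "epoch edge")
})

test_that("angle distributions", {
  topo <- make_topography(1, 1)
  x <- epoched_data(array(rep(topo, 50 * 3), dim = c(60, 50, 3)), 1000, -5)
  a0 <- angle_distribution(topo, x, c(0, 40))
  expect_equal(max(abs(a0$angles_deg)), 0, tolerance = 1e-6)
  # orthogonal data: 90 degrees
  v <- stats::rnorm(60)
  v <- v - sum(v * topo) * topo
  xo <- epoched_data(array(rep(v, 50 * 3), dim = c(60, 50, 3)), 1000, -5)
  a90 <- angle_distribution(topo, xo, c(0, 40))
  expect_equal(stats::median(a90$angles_deg), 90, tolerance = 1e-6)
  # artifact-free neuronal patterns concentrate near 90 degrees
  gt <- gt_small()
  ag <- angle_distribution(unit(stats::rnorm(60)), gt)
  expect_lt(abs(ag$median - 90), 8)
  expect_error(angle_distribution(2 * topo, gt), "unit norm")
})

test_that("real-world-like characterization signature", {
  gt <- gt_small()
  art <- artifact_for(gt, alpha = 0, contrast = 1, seed = 3)
  corrupted <- superpose(gt, art)
  pr <- characterize_artifact(corrupted, reference_data = gt)
  # extracted topography matches the planted one
  expect_gt(abs(sum(pr$topography * art$topography)), 0.99)
  # strong phase locking immediately after the pulse
  early <- gt$times >= 0 & gt$times <= 10
  expect_gt(max(pr$itc$itc[, early]), 0.99)
  expect_gt(mean(pr$itc$itc[, early]), 0.6)
  # artifact topography lies far from the neuronal patterns
  expect_gt(mean(pr$angles$angles_deg > 70, na.rm = TRUE), 0.75)
  expect_equal(pr$angles$n_excluded, 0)
})
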