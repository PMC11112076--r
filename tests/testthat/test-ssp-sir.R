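test_that("high-pass filter contracts", {
  fs <- 5000
  t <- (0:999) / fs
  center <- 300:700 # away from mirror-padded edges
  mk <- function(f) epoched_data(array(rep(sin(2 * pi * f * t + 0.3),
                                           2 * 3),
                                       dim = c(2, 1000, 3)), fs, -50)
  rms <- function(v) sqrt(mean(v^2))
  lo <- highpass_filter(mk(10), 100)
  expect_lt(rms(lo$data[1, center, 1]) / rms(sin(2 * pi * 10 * t)), 0.01)
  hi <- highpass_filter(mk(200), 100)
  expect_lt(abs(rms(hi$data[1, center, 1]) /
                  rms(sin(2 * pi * 200 * t[center])) - 1), 0.01)
  expect_error(highpass_filter(mk(10), 3000), "fs/2")
  # ground-truth data (content <= 80 Hz) nearly vanishes
  gt <- gt_small()
  hp <- highpass_filter(gt, 100)
  expect_lt(rms(hp$data) / rms(gt$data), 0.05)
})

test_that("artifact basis: rank-1 recovery and orthonormality", {
  fs <- 1000
  tc <- simulate_timecourses(0.5, 10, seed = 4, fs = fs)
  topo <- make_topography(1, 3)
  r <- scale_to_p2p(topo, tc, 100)
  x <- epoched_data(tmseegsim:::artifact_tensor(r), fs, -50)
  basis <- estimate_artifact_basis(x)
  expect_gt(abs(sum(basis$U[, 1] * topo)), 0.999)
  expect_lt(max(abs(crossprod(basis$U) - diag(60))), 1e-9)
  expect_true(all(diff(basis$singular_values) <= 1e-9))
  expect_error(estimate_artifact_basis(x, c(500, 600)), "no samples")
})

test_that("artifact-dimension selection: exact, tie-break, simulation", {
  x <- epoched_data(array(stats::rnorm(20 * 50 * 4), dim = c(20, 50, 4)),
                    1000, -10)
  basis <- estimate_artifact_basis(x, c(-10, 30))
  expect_equal(select_artifact_dim(basis, basis$U[, 3]), 3L)
  expect_equal(select_artifact_dim(basis, -basis$U[, 5]), 5L) # sign-proof
  # tie in |cos| breaks to the lowest index
  fake <- list(U = diag(4), singular_values = c(4, 3, 2, 1))
  expect_equal(select_artifact_dim(fake, c(1, 1, 0, 0) / sqrt(2)), 1L)
  expect_error(select_artifact_dim(basis, rep(1, 20)), "unit norm")
  # no topography: top-k by singular value
  expect_equal(select_artifact_dim(basis, NULL, k = 2), 1:2)
  # corrupted dataset: the selected vector matches the true topography
  gt <- gt_small()
  art <- artifact_for(gt, alpha = 0, contrast = 1, seed = 5)
  hp <- highpass_filter(superpose(gt, art), 100)
  b2 <- estimate_artifact_basis(hp)
  sel <- select_artifact_dim(b2, art$topography)
  expect_gt(abs(sum(b2$U[, sel] * art$topography)), 0.95)
})

test_that("projector algebra holds to 1e-9", {
  set.seed(31)
  for (k in c(0, 1, 3)) {
    x <- epoched_data(array(stats::rnorm(30 * 40 * 3), dim = c(30, 40, 3)),
                      1000, -10)
    basis <- estimate_artifact_basis(x, c(-10, 28))
    idx <- if (k == 0) integer(0) else seq_len(k)
    proj <- make_projector(basis, idx)
    P <- proj$P
    expect_lt(max(abs(P %*% P - P)), 1e-9)      # idempotent
    expect_lt(max(abs(P - t(P))), 1e-9)         # symmetric
    expect_equal(sum(diag(P)), 30 - k, tolerance = 1e-9)
    if (k > 0)
      expect_lt(max(abs(P %*% basis$U[, idx])), 1e-9) # annihilation
    if (k == 0) expect_equal(P, diag(30))
  }
  basis <- estimate_artifact_basis(
    epoched_data(array(stats::rnorm(5 * 40 * 2), dim = c(5, 40, 2)),
                 1000, -10), c(-10, 28))
  expect_error(make_projector(basis, 1:5), "every channel")
})

test_that("source-informed reconstruction", {
  lf <- tmseegsim:::default_sir_leadfield()
  L <- lf$gain
  # P = I, data in the lead-field column space: near-identity
  set.seed(17)
  X <- matrix(stats::rnorm(ncol(L) * 50), ncol(L), 50)
  Y <- L %*% X
  y <- epoched_data(array(Y, dim = c(60, 25, 2)), 1000, -10)
  rec <- sir_reconstruct(diag(60), lf, y)
  expect_lt(max(abs(rec$data - y$data)) / max(abs(y$data)), 1e-3)
  # linearity of the operator
  y2 <- epoched_data(array(stats::rnorm(60 * 25 * 2), dim = c(60, 25, 2)),
                     1000, -10)
  r2 <- sir_reconstruct(diag(60), lf, y2)
  ysum <- y; ysum$data <- 2 * y$data + 3 * y2$data
  rsum <- sir_reconstruct(diag(60), lf, ysum)
  expect_equal(rsum$data, 2 * rec$data + 3 * r2$data, tolerance = 1e-9)
  # the rejected artifact does not leak through the SIR filter.  Note that
  # the *output* may legitimately contain energy along the rejected basis
  # vector u: SIR re-estimates neuronal activity through the lead field,
  # restoring neuronal content along u by design.  The leakage statement
  # that is actually guaranteed is (i) the artifact itself is annihilated
  # and (ii) the output u-fraction drops well below the input's.
  gt <- gt_small()
  art <- artifact_for(gt, alpha = 0, contrast = 1, seed = 5)
  corrupted <- superpose(gt, art)
  hp <- highpass_filter(corrupted, 100)
  basis <- estimate_artifact_basis(hp)
  sel <- select_artifact_dim(basis, art$topography)
  proj <- make_projector(basis, sel)
  M <- tmseegsim:::sir_operator(proj$P,
                                sweep(L, 2, colMeans(L)), 1e-3)
  A <- matrix(tmseegsim:::artifact_tensor(art), 60)
  expect_lt(sqrt(sum((M %*% A)^2) / sum(A^2)), 1e-3) # (i)
  rec3 <- sir_reconstruct(proj, lf, corrupted)
  u <- basis$U[, sel]
  mc <- concatenate_trials(corrupted)
  mr <- concatenate_trials(rec3)
  ufrac <- function(m) sqrt(sum(as.numeric(u %*% m)^2) / sum(m^2))
  expect_lt(ufrac(mr), ufrac(mc) / 2) # (ii)
  expect_error(sir_reconstruct(diag(60), L * 0, gt), "degenerate")
})

test_that("windowed application with median blending", {
  gt <- gt_small()
  same <- apply_windowed(gt, gt)
  expect_identical(same$data, gt$data) # cleaned = original
  # sample at 100 ms (far outside window and blend zone) is untouched
  other <- gt
  other$data <- gt$data * 0
  blended <- apply_windowed(gt, other)
  i100 <- which.min(abs(gt$times - 100))
  expect_identical(blended$data[, i100, ], gt$data[, i100, ])
  # inside the window (and away from the blend), the cleaned data stand
  i10 <- which.min(abs(gt$times - 10))
  expect_identical(blended$data[, i10, ], other$data[, i10, ])
  # step discontinuity at the splice is reduced by the median blend
  step_orig <- epoched_data(array(0, dim = c(1, 200, 1)), 1000, -50)
  step_clean <- step_orig
  step_clean$data[] <- 10
  spliced_raw <- step_orig
  idx <- which(step_orig$times >= -10 & step_orig$times <= 30)
  spliced_raw$data[, idx, ] <- 10
  sm <- apply_windowed(step_orig, step_clean)
  edge_jump <- function(v) max(abs(diff(v)))
  expect_lt(edge_jump(sm$data[1, , 1]), edge_jump(spliced_raw$data[1, , 1]))
  expect_error(apply_windowed(gt, gt, window = c(400, 500)), "no samples")
})

test_that("full SSP-SIR cleaning: distortion bounds and artifact removal", {
  gt <- gt_small()
  # intrinsic distortion: with a vanishingly small (1 uV) artifact the
  # high-passed window is still artifact-dominated, selection is clean, and
  # the cost of projecting one dimension stays below 2%
  art1 <- artifact_for(gt, alpha = 0, contrast = 1, amplitude_uv = 1,
                       seed = 5)
  res1 <- clean_dataset_ssp_sir(superpose(gt, art1),
                                known_topography = art1$topography)
  expect_lt(mean_re(res1$data, gt), 0.02)
  expect_equal(res1$k, 1L)
  # strictly zero amplitude is a degenerate case: the high-passed "clean"
  # data contain only low-pass stop-band leakage of neuronal patterns, so
  # the selected dimension is a neuronal direction and projecting it is
  # costly.  Documented, bounded, not silently hidden.
  art0 <- artifact_for(gt, alpha = 0, contrast = 1, seed = 5)
  art0$timecourses[] <- 0
  res0 <- clean_dataset_ssp_sir(superpose(gt, art0),
                                known_topography = art0$topography)
  expect_lt(mean_re(res0$data, gt), 0.15)
  expect_equal(res0$k, 1L)
  # time-locked 250 uV artifact, most dissimilar topography
  art <- artifact_for(gt, alpha = 0, contrast = 1, seed = 5)
  corrupted <- superpose(gt, art)
  res <- clean_dataset_ssp_sir(corrupted,
                               known_topography = art$topography)
  expect_lt(mean_re(res$data, gt), mean_re(corrupted, gt) / 10)
  expect_gt(res$selected_cos, 0.95)
  # late window: everything outside -10..30 ms is left untouched
  expect_lte(100 * mean_re(res$data, gt, c(50, 100)), 0.18)
})

test_that("SSP-SIR is insensitive to inter-trial variability", {
  gt <- gt_small()
  res <- vapply(c(0, 0.5, 1), function(a) {
    art <- artifact_for(gt, alpha = a, contrast = 1 / 100, seed = 7)
    mean_re(clean_dataset_ssp_sir(superpose(gt, art),
                                  known_topography = art$topography)$data,
            gt)
  }, numeric(1))
  expect_lt(max(res) / min(res), 2)
})
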