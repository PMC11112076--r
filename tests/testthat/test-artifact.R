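test_that("wavelet prototype: support, broadband spectrum, zero mean", {
  phi <- wavelet_prototype()
  tt <- attr(phi, "times")
  expect_equal(length(phi), 1000L)
  expect_true(all(phi[tt < 0 | tt > 20] == 0)) # exact support
  expect_lt(abs(mean(phi[tt >= 0 & tt <= 20])) / max(abs(phi)), 0.01)
  sp <- Mod(stats::fft(as.numeric(phi)))^2
  f <- (seq_along(phi) - 1) * 5000 / length(phi)
  keep <- f <= 2500
  expect_gt(sum(sp[keep & f > 100]) / sum(sp[keep]), 0.25)
})

test_that("Eq.-13 time courses across the alpha range", {
  expect_error(simulate_timecourses(1.2, 5), "alpha")
  # alpha = 0: every trial identical to the prototype; rank 1 in time
  tc0 <- simulate_timecourses(0, 8, seed = 2)
  phi <- wavelet_prototype()
  for (i in 1:8) expect_equal(tc0[i, ], as.numeric(phi), tolerance = 1e-12)
  sv <- svd(tc0, nu = 0, nv = 0)$d
  expect_lt(sv[2] / sv[1], 1e-12)
  # determinism
  expect_identical(simulate_timecourses(0.5, 8, seed = 3),
                   simulate_timecourses(0.5, 8, seed = 3))
  # alpha = 1: signs in {-1, 1}, shifts in [0, 10], support within 30 ms
  tc1 <- simulate_timecourses(1, 400, seed = 5)
  expect_true(all(attr(tc1, "signs") %in% c(-1, 1)))
  expect_true(all(attr(tc1, "shifts_ms") >= 0 &
                    attr(tc1, "shifts_ms") <= 10))
  ttc <- attr(tc1, "times")
  expect_true(all(tc1[, ttc < 0 | ttc > 30] == 0)) # exact outside support
  # mean trial much smaller than single trials (Monte-Carlo, 1000 trials)
  tcm <- simulate_timecourses(1, 1000, seed = 6)
  expect_lt(max(abs(colMeans(tcm))) / max(abs(tcm)), 0.15)
  # expected pairwise trial correlation near zero under random signs
  sub <- tc1[1:120, apply(tc1 != 0, 2, any)]
  cc <- suppressWarnings(stats::cor(t(sub)))
  offdiag <- cc[upper.tri(cc)]
  expect_lt(abs(mean(offdiag, na.rm = TRUE)), 0.1)
})

test_that("condition grid enumerates 11 x 11 = 121 conditions", {
  grid <- artifact_conditions()
  expect_equal(nrow(grid), 121L)
  expect_equal(length(unique(grid$alpha)), 11L)
  expect_equal(length(unique(grid$contrast)), 11L)
  expect_true(all(grid$amplitude_uv == 250))
})

test_that("topographies: unit norm, lateralized, contrast controls smoothness", {
  topo <- make_topography(1, 1)
  expect_equal(sum(topo^2), 1, tolerance = 1e-12)
  expect_lt(abs(sum(topo)), 1e-9) # average-referenced
  mont <- build_montage_1020()
  expect_gt(mont$x[which.max(abs(topo))], 0.25)
  expect_error(make_topography(0.5, 1), "contrast")
  expect_error(make_topography(1, 10), "source_index")
  # pairwise spatial-frequency comparison on a dense sphere sampling
  dm <- dense_montage()
  P <- as.matrix(dm[, c("x", "y", "z")])
  r <- vapply(c(1, 1 / 200), function(cc)
    sh_power_ratio(make_topography(cc, 1, montage = dm), P,
                   min_order = 4, max_order = 10), numeric(1))
  expect_lt(r[2], r[1])
})

test_that("peak-to-peak scaling is exact, linear, idempotent", {
  tc <- simulate_timecourses(0.5, 12, seed = 9)
  topo <- make_topography(1, 2)
  r <- scale_to_p2p(topo, tc, 250)
  A <- tmseegsim:::artifact_tensor(r)
  p2p <- max(apply(A, c(1, 3), function(v) max(v) - min(v)))
  expect_equal(p2p, 250, tolerance = 1e-6)
  r2 <- scale_to_p2p(topo, tc, 500)
  expect_equal(r2$timecourses, 2 * r$timecourses, tolerance = 1e-12)
  r3 <- scale_to_p2p(topo, r$timecourses, 250) # re-scaling is idempotent
  expect_equal(r3$timecourses, r$timecourses, tolerance = 1e-12)
  expect_equal(r3$scale, 1, tolerance = 1e-12)
  expect_error(scale_to_p2p(topo, tc * 0, 250), "all-zero")
})

test_that("superposition is additive with provenance", {
  gt <- gt_small()
  art <- artifact_for(gt, alpha = 0, contrast = 1, seed = 3)
  corrupted <- superpose(gt, art)
  expect_equal(corrupted$meta$artifact$alpha, 0)
  # subtracting the realization recovers the ground truth
  expect_equal(corrupted$data - tmseegsim:::artifact_tensor(art), gt$data,
               tolerance = 1e-12)
  # zero-amplitude artifact: bit-exact identity
  zero <- art
  zero$timecourses[] <- 0
  expect_identical(superpose(gt, zero)$data, gt$data)
  # corrupted GMFA dwarfs the clean GMFA for a time-locked 250 uV artifact
  expect_gt(max(compute_gmfa(corrupted)) / max(compute_gmfa(gt)), 10)
  bad <- art
  bad$timecourses <- bad$timecourses[, -1]
  expect_error(superpose(gt, bad), "shapes")
})

test_that("signal-space angles: exact cases and high-dim concentration", {
  u <- unit(stats::rnorm(60))
  expect_equal(signal_space_angle(u, u), 0, tolerance = 1e-6)
  expect_equal(signal_space_angle(u, -u), 180, tolerance = 1e-6)
  v <- stats::rnorm(60)
  v <- unit(v - sum(v * u) * u)
  expect_equal(signal_space_angle(u, v), 90, tolerance = 1e-6)
  expect_error(signal_space_angle(u, u * 0), "zero vector")
  # random 60-dim Gaussian pairs concentrate near 90 degrees
  set.seed(13)
  ang <- replicate(1e4, signal_space_angle(stats::rnorm(60),
                                           stats::rnorm(60)))
  expect_lt(abs(mean(ang) - 90), 3)
})

test_that("angle profile between topography and evoked data", {
  gt <- gt_small()
  topo <- make_topography(1, 1)
  pr <- topography_angle_profile(topo, gt)
  expect_true(all(pr$angles_deg >= 0 & pr$angles_deg <= 180))
  expect_lte(pr$p5_deg, min(pr$angles_deg) + 1e-9 +
               diff(range(pr$angles_deg))) # p5 within the observed range
  expect_gte(pr$p5_deg, min(pr$angles_deg))
  expect_error(topography_angle_profile(2 * topo, gt), "unit norm")
  # v = u at some time point gives angle exactly 0 there
  x <- gt
  x$data[, 10, ] <- topo * 5
  pr2 <- topography_angle_profile(topo, x, window = c(gt$times[10],
                                                      gt$times[10]))
  expect_equal(pr2$angles_deg, 0, tolerance = 1e-6)
})
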