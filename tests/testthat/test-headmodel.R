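test_that("homogeneous-sphere limit matches the analytic closed form", {
  mont <- build_montage_1020()
  E <- as.matrix(mont[, c("x", "y", "z")])
  model <- spherical_head_model(conductivities = c(1, 1, 1))
  set.seed(21)
  for (k in 1:8) {
    r0 <- stats::rnorm(3)
    r0 <- r0 / sqrt(sum(r0^2)) * stats::runif(1, 15, 64)
    p <- stats::rnorm(3)
    got <- forward_potential(model, r0, p, mont)
    want <- apply(E, 1, function(e)
      oracle_hom_sphere_potential(p, r0, e, model$radii_mm[3]))
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-3)
  }
  # transfer coefficients reduce to (2n+1)/n
  n <- seq_len(model$series_terms)
  expect_equal(model$transfer, (2 * n + 1) / n, tolerance = 1e-10)
})

test_that("forward solution is linear and rotation-equivariant", {
  mont <- build_montage_1020()
  model <- spherical_head_model()
  r0 <- c(20, 10, 55)
  p <- c(1, -2, 0.5)
  expect_equal(forward_potential(model, r0, c(0, 0, 0), mont),
               rep(0, 60))
  v1 <- forward_potential(model, r0, p, mont)
  expect_equal(forward_potential(model, r0, 2 * p, mont), 2 * v1,
               tolerance = 1e-12)
  # superposition over random probe pairs
  set.seed(3)
  for (k in 1:5) {
    q <- stats::rnorm(3)
    vq <- forward_potential(model, r0, q, mont)
    expect_equal(forward_potential(model, r0, p + q, mont), v1 + vq,
                 tolerance = 1e-9)
  }
  # rotation equivariance about z: rotating dipole position, moment and
  # electrodes together leaves potentials unchanged
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  E <- as.matrix(mont[, c("x", "y", "z")])
  v_rot <- forward_potential(model, as.numeric(Rz %*% r0),
                             as.numeric(Rz %*% p), E %*% t(Rz))
  expect_equal(v_rot, v1, tolerance = 1e-9)
})

test_that("head model validation errors", {
  expect_error(spherical_head_model(radii_mm = c(85, 80, 92)), "increasing")
  expect_error(spherical_head_model(conductivities = c(1, -1, 1)),
               "positive")
  expect_error(spherical_head_model(series_terms = 10), ">= 20")
  model <- spherical_head_model()
  mont <- build_montage_1020()
  expect_error(forward_potential(model, c(0, 0, 85), c(1, 0, 0), mont),
               "inside the brain")
  expect_error(forward_potential(model, c(0, 0, 0), c(1, 0, 0), mont),
               "center")
})

test_that("lead field assembly: reference, depth, row permutation", {
  mont <- build_montage_1020()
  model <- spherical_head_model()
  src <- source_space(rbind(c(0, 0, 20), c(0, 0, 64)),
                      rbind(c(1, 0, 0), c(1, 0, 0)))
  lf <- compute_leadfield(model, src, mont)
  expect_true(all(abs(colSums(lf$gain)) < 1e-9 * max(abs(lf$gain))))
  # deep medial dipole yields lower peak amplitude than superficial
  expect_lt(max(abs(lf$gain[, 1])), max(abs(lf$gain[, 2])))
  # permuting electrodes permutes rows identically
  perm <- sample(60)
  mont_p <- mont[perm, ]
  lf_p <- compute_leadfield(model, src, mont_p)
  expect_equal(lf_p$gain, lf$gain[perm, ], tolerance = 1e-12)
  # unreferenced flag
  lf_u <- compute_leadfield(model, src, mont, average_reference = FALSE)
  expect_gt(max(abs(colSums(lf_u$gain))), 0)
  # sources outside the brain sphere rejected
  expect_error(
    compute_leadfield(model, source_space(rbind(c(0, 0, 81)),
                                          rbind(c(1, 0, 0))), mont),
    "inside the brain")
})

test_that("artifact sources: nine right-lateral tangential dipoles", {
  src <- sample_artifact_sources(seed = 1L)
  expect_equal(nrow(src$positions_mm), 9)
  expect_true(all(src$positions_mm[, 1] > 0))
  expect_true(all(sqrt(rowSums(src$positions_mm^2)) < 80))
  expect_equal(sqrt(rowSums(src$orientations^2)), rep(1, 9),
               tolerance = 1e-9)
  # tangential: orientation orthogonal to the position vector
  dots <- rowSums(src$positions_mm * src$orientations) /
    sqrt(rowSums(src$positions_mm^2))
  expect_true(all(abs(dots) < 1e-9))
  expect_identical(src, sample_artifact_sources(seed = 1L))
  # resulting topographies are bipolar and right-lateralized
  mont <- build_montage_1020()
  lf <- compute_leadfield(artifact_head_model(1), src, mont)
  for (i in 1:9) {
    topo <- lf$gain[, i]
    expect_gt(mont$x[which.max(abs(topo))], 0.25)       # right-lateral
    # bipolar: substantial deflections of both signs (tangential dipoles
    # through an average-referenced montage; threshold measured at 0.08)
    expect_lt(min(topo) / max(abs(topo)), -0.05)
    expect_gt(max(topo) / max(abs(topo)), 0.05)
  }
})

test_that("decreasing skull conductivity lowers spatial frequency monotonically", {
  dm <- dense_montage()
  src <- sample_artifact_sources(seed = 1L)
  P <- montage_positions <- as.matrix(dm[, c("x", "y", "z")])
  ratios <- vapply(default_contrasts(), function(cc) {
    m <- artifact_head_model(cc)
    mean(vapply(1:9, function(i) {
      v <- forward_potential(m, src$positions_mm[i, ],
                             src$orientations[i, ], P)
      sh_power_ratio(v - mean(v), P, min_order = 4, max_order = 10)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_gt(ratios[1] / ratios[11], 5) # strong smearing at 1/200
})
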