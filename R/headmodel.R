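# Three-layer concentric-sphere EEG forward model.
#
# The potential of a current dipole inside the innermost (brain) sphere is
# expanded in a Legendre series.  In each shell the per-degree radial
# solution is a_j r^n + b_j r^-(n+1); the dipole source contributes the
# singular term only in the brain compartment.  Boundary conditions
# (continuity of potential and of radial current at the two interfaces,
# zero radial current at the scalp surface) give a 5x5 linear system per
# degree n, solved once per model and cached as per-degree transfer
# coefficients.  With all conductivities equal, the transfer coefficient
# reduces to the homogeneous-sphere value (2n+1)/n, which the test suite
# verifies against the analytic closed form.

#' Construct a three-layer spherical head model
#'
#' @param radii_mm radii of the brain, skull and scalp spheres in mm,
#'   strictly increasing.
#' @param conductivities relative conductivities of brain, skull and scalp
#'   (positive).  The convention used throughout the package is
#'   brain = scalp = 1 with the skull set to a skull-to-skin/brain contrast
#'   value (1 down to 1/200).
#' @param series_terms truncation order of the Legendre series (>= 20).
#'   60 suffices for sources down to about 85% of the brain radius; the
#'   superficial artifact sources use 80 (see [artifact_head_model()]).
#' @return an object of class `spherical_head_model`.
#' @export
spherical_head_model <- function(radii_mm = c(80, 85, 92),
                                 conductivities = c(1, 1 / 50, 1),
                                 series_terms = 60) {
  stopifnot(length(radii_mm) == 3, length(conductivities) == 3)
  if (any(diff(radii_mm) <= 0)) stop("radii must be strictly increasing")
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  if (!is_count(series_terms) || series_terms < 20)
    stop("series_terms must be an integer >= 20")
  m <- list(radii_mm = as.numeric(radii_mm),
            conductivities = as.numeric(conductivities),
            series_terms = as.integer(series_terms))
  m$transfer <- transfer_coefficients(m)
  class(m) <- "spherical_head_model"
  m
}

#' @export
print.spherical_head_model <- function(x, ...) {
  cat("Three-layer spherical head model\n")
  cat("  radii (brain/skull/scalp):", paste(x$radii_mm, collapse = "/"),
      "mm\n")
  cat("  relative conductivities:",
      paste(signif(x$conductivities, 4), collapse = "/"), "\n")
  cat("  Legendre series terms:", x$series_terms, "\n")
  invisible(x)
}

# Per-degree transfer coefficients F_n: the scalp-surface radial factor of
# the unit source harmonic, normalized so that F_n = (2n+1)/n for a
# homogeneous sphere.
transfer_coefficients <- function(model) {
  rho <- model$radii_mm / model$radii_mm[3] # normalized radii; rho[3] = 1
  s <- model$conductivities
  N <- model$series_terms
  Fn <- numeric(N)
  for (n in seq_len(N)) {
    r1n <- rho[1]^n; r1m <- rho[1]^(-(n + 1))
    r2n <- rho[2]^n; r2m <- rho[2]^(-(n + 1))
    # unknowns: a1, a2, b2, a3, b3 (source coefficient = 1 in layer 1)
    A <- matrix(0, 5, 5)
    b <- numeric(5)
    # potential continuity at rho1
    A[1, ] <- c(r1n, -r1n, -r1m, 0, 0); b[1] <- -r1m
    # radial current continuity at rho1 (common factor rho1 dropped)
    A[2, ] <- c(s[1] * n * r1n, -s[2] * n * r1n, s[2] * (n + 1) * r1m, 0, 0)
    b[2] <- s[1] * (n + 1) * r1m
    # potential continuity at rho2
    A[3, ] <- c(0, r2n, r2m, -r2n, -r2m)
    # radial current continuity at rho2
    A[4, ] <- c(0, s[2] * n * r2n, -s[2] * (n + 1) * r2m,
                -s[3] * n * r2n, s[3] * (n + 1) * r2m)
    # insulating outer boundary at rho = 1
    A[5, ] <- c(0, 0, 0, n, -(n + 1))
    x <- solve(A, b)
    Fn[n] <- x[4] + x[5] # surface potential factor for unit source term
  }
  Fn
}

# Per-degree series sums shared by all dipole moments at one location:
#   V(e) = C * [ (p . bhat) S1_e + (p . (ehat - u_e bhat)) S2_e ],
#   S1_e = sum_n F_n beta^(n-1) n P_n(u_e),
#   S2_e = sum_n F_n beta^(n-1) P_n'(u_e),
# with beta = |dipole| / scalp radius, u_e = ehat . bhat and
# C = 1 / (4 pi sigma_brain R^2).
forward_series <- function(model, dipole_pos_mm, electrode_units,
                           tail_tol = 1e-2) {
  R <- model$radii_mm[3]
  b <- vnorm(dipole_pos_mm)
  if (b >= model$radii_mm[1])
    stop("dipole must lie strictly inside the brain sphere")
  if (b < 1e-9)
    stop("dipole at the sphere center is not supported")
  bhat <- dipole_pos_mm / b
  beta <- b / R
  u <- as.numeric(electrode_units %*% bhat)
  u <- pmax(-1, pmin(1, u))
  N <- model$series_terms
  lt <- legendre_table(u, N)
  w <- model$transfer * beta^(seq_len(N) - 1)
  S1 <- as.numeric(lt$P %*% (w * seq_len(N)))
  S2 <- as.numeric(lt$dP %*% w)
  # tail check: the last retained term must be negligible
  tail_rel <- max(abs(w[N]) * max(abs(lt$P[, N]) * N + abs(lt$dP[, N]))) /
    max(max(abs(S1)), max(abs(S2)), .Machine$double.eps)
  if (tail_rel > tail_tol)
    stop("Legendre series not converged after ", N,
         " terms (relative tail ", signif(tail_rel, 2),
         "); increase series_terms")
  list(S1 = S1, S2 = S2, u = u, bhat = bhat,
       C = 1 / (4 * pi * model$conductivities[1] * R^2))
}

#' Scalp potential of a current dipole in the layered sphere
#'
#' @param model a [spherical_head_model()].
#' @param dipole_pos_mm dipole location (3-vector, mm), strictly inside the
#'   brain sphere.
#' @param dipole_moment dipole moment (3-vector, arbitrary units; the
#'   potential is linear in the moment).
#' @param electrode_pos electrode positions: an `eeg_montage`, or a matrix
#'   of unit vectors (n x 3) which are scaled to the scalp surface.
#' @return potential at each electrode (numeric vector).
#' @export
forward_potential <- function(model, dipole_pos_mm, dipole_moment,
                              electrode_pos) {
  E <- if (inherits(electrode_pos, "eeg_montage"))
    montage_positions(electrode_pos)
  else if (is.matrix(electrode_pos)) electrode_pos
  else matrix(electrode_pos, ncol = 3)
  E <- E / sqrt(rowSums(E^2))
  fs <- forward_series(model, dipole_pos_mm, E)
  pr <- sum(dipole_moment * fs$bhat)
  Tt <- as.numeric(E %*% dipole_moment) - fs$u * pr
  fs$C * (pr * fs$S1 + Tt * fs$S2)
}

#' Define a dipole source space
#'
#' @param positions_mm n x 3 matrix of dipole locations (mm, head-centered).
#' @param orientations n x 3 matrix of unit orientation vectors.
#' @return an object of class `source_space`.
#' @export
source_space <- function(positions_mm, orientations) {
  positions_mm <- as.matrix(positions_mm)
  orientations <- as.matrix(orientations)
  stopifnot(ncol(positions_mm) == 3, ncol(orientations) == 3,
            nrow(positions_mm) == nrow(orientations))
  nn <- sqrt(rowSums(orientations^2))
  if (any(abs(nn - 1) > 1e-6)) stop("orientations must be unit vectors")
  out <- list(positions_mm = positions_mm, orientations = orientations)
  class(out) <- "source_space"
  out
}

#' Assemble a lead field from a head model, source space and montage
#'
#' Columns are the scalp potentials of unit dipoles, one per source-space
#' entry.  With `average_reference = TRUE` every column is re-referenced to
#' the channel average (column sums are zero).
#'
#' @param model a [spherical_head_model()].
#' @param sources a [source_space()].
#' @param montage an `eeg_montage`.
#' @param average_reference logical; apply average reference (default TRUE).
#' @return an object of class `leadfield`: list with elements `gain`
#'   (channels x sources), `montage`, `sources`, `average_reference`.
#' @export
compute_leadfield <- function(model, sources, montage,
                              average_reference = TRUE) {
  E <- montage_positions(montage)
  E <- E / sqrt(rowSums(E^2))
  P <- sources$positions_mm
  O <- sources$orientations
  if (any(sqrt(rowSums(P^2)) >= model$radii_mm[1]))
    stop("all sources must lie strictly inside the brain sphere")
  G <- matrix(0, nrow(E), nrow(P))
  i <- 1L
  while (i <= nrow(P)) {
    fs <- forward_series(model, P[i, ], E)
    # all sources sharing this location reuse the series sums
    j <- i
    while (j <= nrow(P) && isTRUE(all.equal(P[j, ], P[i, ],
                                            tolerance = 1e-12))) {
      pr <- sum(O[j, ] * fs$bhat)
      Tt <- as.numeric(E %*% O[j, ]) - fs$u * pr
      G[, j] <- fs$C * (pr * fs$S1 + Tt * fs$S2)
      j <- j + 1L
    }
    i <- j
  }
  if (average_reference) G <- sweep(G, 2, colMeans(G))
  out <- list(gain = G, montage = montage, sources = sources,
              average_reference = isTRUE(average_reference))
  class(out) <- "leadfield"
  out
}

#' @export
print.leadfield <- function(x, ...) {
  cat("Lead field:", nrow(x$gain), "channels x", ncol(x$gain), "sources;",
      if (x$average_reference) "average-referenced" else "unreferenced", "\n")
  invisible(x)
}

#' Sample the nine right-lateral artifact source dipoles
#'
#' Nine superficial, tangentially oriented dipoles on the right side of the
#' head, the generators of the simulated muscle-artifact topographies.
#' Base directions form a 3 x 3 grid over the right lateral surface
#' (polar 50/70/90 degrees, azimuth -20/0/20 degrees from the +x axis) with
#' a small seeded angular jitter; orientation is drawn uniformly in the
#' tangent plane.  Deterministic given the seed.
#'
#' @param seed RNG seed.
#' @param brain_radius_mm brain sphere radius; sources sit at
#'   `depth_frac` times this radius.
#' @param depth_frac fractional source depth (default 0.93: superficial).
#' @return a [source_space()] with 9 entries, all with positive x.
#' @export
sample_artifact_sources <- function(seed = 1L, brain_radius_mm = 80,
                                    depth_frac = 0.93) {
  grid <- expand.grid(polar = c(50, 70, 90), azim = c(20, 0, -20))
  P <- matrix(0, 9, 3)
  O <- matrix(0, 9, 3)
  with_seed(seed, {
    for (i in 1:9) {
      p <- grid$polar[i] + stats::runif(1, -5, 5)
      a <- grid$azim[i] + stats::runif(1, -5, 5)
      d <- pos_sph(p, a) # azimuth 0 points to +x (right ear)
      pos <- d * brain_radius_mm * depth_frac
      ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      t1 <- unit(ref - sum(ref * d) * d)
      t2 <- c(d[2] * t1[3] - d[3] * t1[2],
              d[3] * t1[1] - d[1] * t1[3],
              d[1] * t1[2] - d[2] * t1[1])
      psi <- stats::runif(1, 0, 2 * pi)
      P[i, ] <- pos
      O[i, ] <- cos(psi) * t1 + sin(psi) * t2
    }
  })
  source_space(P, O)
}

#' Head model used for simulating artifact topographies
#'
#' Same geometry as the default model but with the skull conductivity set
#' to the requested skull-to-skin/brain contrast and a higher series order
#' (80), needed for the very superficial artifact sources.
#'
#' @param contrast skull-to-skin/brain conductivity contrast.
#' @param series_terms Legendre series order.
#' @return a [spherical_head_model()].
#' @export
artifact_head_model <- function(contrast, series_terms = 80) {
  spherical_head_model(conductivities = c(1, contrast, 1),
                       series_terms = series_terms)
}

#' Distributed source space for source-informed reconstruction
#'
#' A quasi-uniform shell of free-orientation dipoles (three orthogonal
#' unit dipoles per location) at 85% of the brain radius, covering the
#' upper part of the brain down to z = -0.3 of the shell radius.
#'
#' @param n_locations number of dipole locations before the z cut.
#' @param brain_radius_mm brain sphere radius (mm).
#' @param radius_frac shell radius as a fraction of the brain radius.
#' @param zmin_frac keep locations with z above this fraction of the shell
#'   radius.
#' @return a [source_space()] with 3 entries per retained location.
#' @export
sir_source_space <- function(n_locations = 240, brain_radius_mm = 80,
                             radius_frac = 0.85, zmin_frac = -0.3) {
  pts <- fibonacci_sphere(n_locations)
  pts <- pts[pts[, 3] > zmin_frac, , drop = FALSE]
  r <- brain_radius_mm * radius_frac
  P <- pts[rep(seq_len(nrow(pts)), each = 3), ] * r
  O <- do.call(rbind, rep(list(diag(3)), nrow(pts)))
  source_space(P, O)
}

# default SIR lead field (60-channel montage, reference model), cached
default_sir_leadfield <- function() {
  key <- "sir_leadfield_default"
  if (!is.null(.tmseegsim_cache[[key]])) return(.tmseegsim_cache[[key]])
  lf <- compute_leadfield(spherical_head_model(), sir_source_space(),
                          build_montage_1020(60))
  .tmseegsim_cache[[key]] <- lf
  lf
}

# --- spatial-frequency diagnostics -----------------------------------------

# real spherical-harmonic basis evaluated at unit positions, degrees 1..lmax
real_sh_basis <- function(positions, lmax) {
  P <- positions / sqrt(rowSums(positions^2))
  th <- acos(pmax(-1, pmin(1, P[, 3])))
  ph <- atan2(P[, 2], P[, 1])
  u <- cos(th)
  n <- nrow(P)
  cols <- list()
  deg <- integer(0)
  # associated Legendre via recursions (Condon-Shortley phase included)
  Plm <- array(0, dim = c(n, lmax + 1, lmax + 1)) # [point, l+1, m+1]
  Plm[, 1, 1] <- 1
  s <- sqrt(pmax(0, 1 - u^2))
  for (l in 1:lmax) {
    # P_l^l = -(2l-1) s P_{l-1}^{l-1}
    Plm[, l + 1, l + 1] <- -(2 * l - 1) * s * Plm[, l, l]
    # P_l^{l-1} = (2l-1) u P_{l-1}^{l-1}
    Plm[, l + 1, l] <- (2 * l - 1) * u * Plm[, l, l]
    if (l >= 2) for (m in 0:(l - 2)) {
      Plm[, l + 1, m + 1] <- ((2 * l - 1) * u * Plm[, l, m + 1] -
                                (l + m - 1) * Plm[, l - 1, m + 1]) / (l - m)
    }
  }
  for (l in 1:lmax) {
    for (m in 0:l) {
      nf <- sqrt((2 * l + 1) / (4 * pi) *
                   exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      if (m == 0) {
        cols[[length(cols) + 1]] <- nf * Plm[, l + 1, 1]
        deg <- c(deg, l)
      } else {
        cols[[length(cols) + 1]] <- sqrt(2) * nf * Plm[, l + 1, m + 1] *
          cos(m * ph)
        cols[[length(cols) + 1]] <- sqrt(2) * nf * Plm[, l + 1, m + 1] *
          sin(m * ph)
        deg <- c(deg, l, l)
      }
    }
  }
  B <- do.call(cbind, cols)
  attr(B, "degree") <- deg
  B
}

#' Fraction of topography power in high spherical-harmonic degrees
#'
#' Least-squares fit of a scalp topography onto real spherical harmonics of
#' degree 1..`max_order` at the sampling positions; returns the fraction of
#' fitted coefficient power carried by degrees >= `min_order`.  Used to
#' quantify how decreasing skull conductivity smears topographies toward
#' low spatial frequencies.
#'
#' Note: on a 60-electrode upper-head cap the fit of degrees beyond ~6 is
#' ill-posed and spectral leakage can mask the trend; for quantitative
#' spatial-frequency comparisons evaluate the topography on a dense
#' full-sphere sampling (e.g. [fibonacci_sphere()] positions passed through
#' [forward_potential()]) and fit a higher `max_order`.
#'
#' @param topography potential vector sampled at `positions`.
#' @param positions an `eeg_montage` or an n x 3 matrix of unit positions.
#' @param min_order lowest degree counted as "high" spatial frequency.
#' @param max_order maximal fitted degree.
#' @return a fraction in \[0, 1\].
#' @export
sh_power_ratio <- function(topography, positions, min_order = 4,
                           max_order = 6) {
  P <- if (inherits(positions, "eeg_montage")) montage_positions(positions)
  else as.matrix(positions)
  B <- real_sh_basis(P, max_order)
  cf <- qr.coef(qr(B), as.numeric(topography))
  cf[is.na(cf)] <- 0
  deg <- attr(B, "degree")
  sum(cf[deg >= min_order]^2) / sum(cf^2)
}

#' @rdname sh_power_ratio
#' @param n number of points.
#' @export
fibonacci_sphere_points <- function(n) fibonacci_sphere(n)
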