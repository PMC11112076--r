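# Theoretical 10-20 / 10-10 electrode montages on the unit sphere.
#
# Construction follows the classical arc rule: nasion, inion and the
# pre-auricular points sit on the equator of the scalp sphere, the outer
# 10% ring lies at a polar angle of 72 degrees from the vertex, and
# intermediate electrodes are placed at equal fractions along the great
# circle between the midline electrode of a row and its outer-ring end.
# Coordinates are head-centered Cartesian: +x right, +y anterior,
# +z superior; Cz is the vertex (0, 0, 1).

pos_sph <- function(polar_deg, azim_deg) {
  p <- polar_deg * pi / 180
  a <- azim_deg * pi / 180
  c(sin(p) * cos(a), sin(p) * sin(a), cos(p))
}

# spherical linear interpolation between unit vectors
slerp <- function(u, v, f) {
  w <- acos(max(-1, min(1, sum(u * v))))
  if (w < 1e-12) return(u)
  (sin((1 - f) * w) * u + sin(f * w) * v) / sin(w)
}

montage_1020_60 <- function() {
  pos <- list()
  # outer 10% ring: polar 72 deg, every 18 deg of azimuth starting at the
  # front (azimuth 90 = nasion direction) and stepping over the right side
  ring_labels <- c("Fpz", "Fp2", "AF8", "F8", "FT8", "T8", "TP8", "P8",
                   "PO8", "O2", "Oz", "O1", "PO7", "P7", "TP7", "T7",
                   "FT7", "F7", "AF7", "Fp1")
  for (k in seq_along(ring_labels))
    pos[[ring_labels[k]]] <- pos_sph(72, 90 - 18 * (k - 1))
  # midline (sagittal arc), 18-degree steps from the vertex
  pos[["Fz"]]  <- pos_sph(36, 90)
  pos[["FCz"]] <- pos_sph(18, 90)
  pos[["Cz"]]  <- c(0, 0, 1)
  pos[["CPz"]] <- pos_sph(18, -90)
  pos[["Pz"]]  <- pos_sph(36, -90)
  pos[["POz"]] <- pos_sph(54, -90)
  # rows: equal arc fractions between the midline electrode and the ring end
  row_spec <- list(
    F  = list(mid = "Fz",  left = "F7",  right = "F8",
              lab = c("1", "3", "5"), frac = c(0.25, 0.5, 0.75)),
    FC = list(mid = "FCz", left = "FT7", right = "FT8",
              lab = c("1", "3", "5"), frac = c(0.25, 0.5, 0.75)),
    C  = list(mid = "Cz",  left = "T7",  right = "T8",
              lab = c("1", "3", "5"), frac = c(0.25, 0.5, 0.75)),
    CP = list(mid = "CPz", left = "TP7", right = "TP8",
              lab = c("1", "3", "5"), frac = c(0.25, 0.5, 0.75)),
    P  = list(mid = "Pz",  left = "P7",  right = "P8",
              lab = c("1", "3", "5"), frac = c(0.25, 0.5, 0.75)),
    AF = list(mid = NULL,  left = "AF7", right = "AF8",
              lab = "3", frac = 0.5, mid_pos = pos_sph(54, 90)),
    PO = list(mid = "POz", left = "PO7", right = "PO8",
              lab = "3", frac = 0.5)
  )
  for (row in names(row_spec)) {
    sp <- row_spec[[row]]
    mid <- if (is.null(sp$mid)) sp$mid_pos else pos[[sp$mid]]
    for (j in seq_along(sp$frac)) {
      f <- sp$frac[j]
      odd <- as.integer(sp$lab[j])          # left labels are odd
      pos[[paste0(row, odd)]] <- slerp(mid, pos[[sp$left]], f)
      pos[[paste0(row, odd + 1)]] <- slerp(mid, pos[[sp$right]], f)
    }
  }
  pos
}

montage_labels_30 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FCz", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CPz", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2")
}

#' Build the theoretical 10-20 electrode montage
#'
#' Returns the deterministic, right/left-symmetric theoretical montage used
#' throughout the package: 60 channels of the extended 10-20 (10-10) system
#' on the unit scalp sphere, or its classical 30-channel subset used for
#' montage-extrapolation tests.  In the 60-channel montage the labels
#' `F3`, `C3`, ... denote electrodes at equal arc fractions between the
#' midline and the 10% ring (`C5` is three quarters of the way to `T7`).
#'
#' @param n_channels number of channels; 60 (default) or 30.
#' @return a data.frame of class `eeg_montage` with columns
#'   `label`, `x`, `y`, `z` (unit-norm positions; +x right, +y anterior,
#'   +z superior).
#' @examples
#' m <- build_montage_1020()
#' stopifnot(nrow(m) == 60, abs(sum(m[m$label == "Cz", c("x","y","z")]^2) - 1) < 1e-9)
#' @export
build_montage_1020 <- function(n_channels = 60) {
  if (!is_count(n_channels) || !(n_channels %in% c(30L, 60L)))
    stop("unsupported channel count: ", n_channels, " (supported: 60, 30)")
  pos <- montage_1020_60()
  labels <- names(pos)
  if (n_channels == 30) {
    labels <- montage_labels_30()
    pos <- pos[labels]
  }
  m <- do.call(rbind, pos)
  m <- m / sqrt(rowSums(m^2)) # unit norm by construction; enforce exactly
  out <- data.frame(label = labels, x = m[, 1], y = m[, 2], z = m[, 3],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("eeg_montage", "data.frame")
  out
}

montage_positions <- function(montage) {
  stopifnot(all(c("label", "x", "y", "z") %in% names(montage)))
  as.matrix(montage[, c("x", "y", "z")])
}

#' Perturb electrode positions tangentially
#'
#' Applies a fixed-seed tangential jitter to each electrode (uniform in
#' \[-jitter_mm, jitter_mm\] along two tangent directions, then re-projected
#' to the unit sphere).  Used to build the artifact-topography head model
#' from a *different* electrode geometry than the one used inside SSP-SIR,
#' avoiding an inverse crime.
#'
#' @param montage an `eeg_montage`.
#' @param jitter_mm maximal tangential displacement in millimetres.
#' @param seed RNG seed (fixed default so the perturbed montage is a
#'   deterministic part of the simulated world).
#' @param scalp_radius_mm scalp sphere radius used to convert mm to radians.
#' @return a perturbed `eeg_montage`.
#' @export
perturb_montage <- function(montage, jitter_mm = 5, seed = 20240509L,
                            scalp_radius_mm = 92) {
  P <- montage_positions(montage)
  with_seed(seed, {
    for (i in seq_len(nrow(P))) {
      p <- P[i, ]
      ref <- if (abs(p[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      t1 <- unit(ref - sum(ref * p) * p)
      t2 <- c(p[2] * t1[3] - p[3] * t1[2],
              p[3] * t1[1] - p[1] * t1[3],
              p[1] * t1[2] - p[2] * t1[1])
      d <- stats::runif(2, -jitter_mm, jitter_mm) / scalp_radius_mm
      P[i, ] <- unit(p + d[1] * t1 + d[2] * t2)
    }
  })
  out <- montage
  out$x <- P[, 1]; out$y <- P[, 2]; out$z <- P[, 3]
  out
}

#' Write / read a montage as CSV
#'
#' Plain-text exchange format: columns `label,x,y,z` on the unit sphere.
#' @param montage an `eeg_montage`.
#' @param path file path.
#' @return `read_montage` returns an `eeg_montage`.
#' @export
write_montage <- function(montage, path) {
  utils::write.csv(as.data.frame(montage), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("montage file must have columns label,x,y,z")
  if (anyDuplicated(d$label)) stop("duplicate channel labels in montage file")
  nrm <- sqrt(d$x^2 + d$y^2 + d$z^2)
  if (any(abs(nrm - 1) > 1e-6))
    stop("montage positions must lie on the unit sphere")
  class(d) <- c("eeg_montage", "data.frame")
  d
}
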