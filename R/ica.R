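# FastICA component subtraction.
#
# Symmetric (parallel) FastICA with the tanh contrast function, run on all
# trials concatenated, followed by subtraction of the single independent
# component whose mixing-matrix column best matches the known simulated
# artifact topography.  Implemented in-package: whitening by eigenvalue
# decomposition of the channel covariance, fixed-point updates with
# symmetric decorrelation, seeded initialization.

#' FastICA decomposition (symmetric, tanh contrast)
#'
#' @param mat channels x observations matrix (e.g. from
#'   [concatenate_trials()]).
#' @param n_components number of components; reduced with a warning if the
#'   data rank is lower.
#' @param seed RNG seed for the initial unmixing matrix.
#' @param tol convergence tolerance on the fixed-point update (maximal
#'   deviation of `|diag(W_new W_old')|` from 1).
#' @param max_iter iteration cap; non-convergence is reported in the
#'   `converged` flag, not an error.
#' @return an object of class `ica_decomposition`: list with `mixing`
#'   (channels x components), `sources` (components x observations),
#'   `row_means`, `converged`, `n_iter`, `seed`.  `mixing %*% sources`
#'   reconstructs the centered input (exactly, when `n_components` equals
#'   the data rank).
#' @export
fastica_decompose <- function(mat, n_components = nrow(mat), seed = 1L,
                              tol = 1e-6, max_iter = 1000) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  nch <- nrow(mat)
  nobs <- ncol(mat)
  if (!is_count(n_components) || n_components > nch)
    stop("n_components must be a count <= channels")
  rm_ <- rowMeans(mat)
  X <- mat - rm_
  C <- tcrossprod(X) / nobs
  eg <- eigen(C, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  rank <- sum(pos)
  r <- n_components
  if (rank < n_components) {
    warning("data rank ", rank, " < n_components ", n_components,
            "; reducing")
    r <- rank
  }
  vals <- eg$values[seq_len(r)]
  vecs <- eg$vectors[, seq_len(r), drop = FALSE]
  K <- t(vecs) / sqrt(vals)          # whitening, r x channels
  Kinv <- vecs * rep(sqrt(vals), each = nch) # channels x r
  Xw <- K %*% X
  sym_decorr <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    ev <- pmax(e$values, .Machine$double.eps)
    (e$vectors %*% (t(e$vectors) / sqrt(ev))) %*% W
  }
  W <- with_seed(seed, matrix(stats::rnorm(r * r), r, r))
  W <- sym_decorr(W)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Y <- W %*% Xw
    G <- tanh(Y)
    gprime <- rowMeans(1 - G * G)
    W1 <- tcrossprod(G, Xw) / nobs - gprime * W
    W1 <- sym_decorr(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  S <- W %*% Xw
  A <- Kinv %*% t(W)
  out <- list(mixing = A, sources = S, row_means = rm_,
              n_components = r, converged = converged, n_iter = it,
              seed = seed, tol = tol)
  class(out) <- "ica_decomposition"
  out
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat("FastICA decomposition:", nrow(x$mixing), "channels,",
      x$n_components, "components;",
      if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations\n")
  invisible(x)
}

#' Select the independent component matching a known topography
#'
#' Index of the mixing-matrix column with the largest absolute cosine
#' similarity to the known artifact topography (ICA sign/scale
#' indeterminacy makes the absolute value necessary); ties break to the
#' lowest index.
#'
#' @param decomp an `ica_decomposition`.
#' @param known_topography unit-norm channel vector.
#' @return integer component index.
#' @export
select_artifact_component <- function(decomp, known_topography) {
  if (abs(vnorm(known_topography) - 1) > 1e-6)
    stop("known_topography must be unit norm")
  A <- decomp$mixing
  nrm <- sqrt(colSums(A^2))
  nrm[nrm == 0] <- Inf
  cosv <- abs(as.numeric(crossprod(A, known_topography))) / nrm
  which.max(cosv)
}

#' Remove one independent component from epoched data
#'
#' Subtracts `mixing[, index] %*% sources[index, ]` mapped back onto the
#' epochs.  Removing an all-zero component is the identity.
#'
#' @param data the `epoched_data` the decomposition was computed from.
#' @param decomp an `ica_decomposition`.
#' @param index component to remove.
#' @return an object of class `cleaning_result` (see
#'   [clean_dataset_ssp_sir()]) with `method = "ica"`.
#' @export
remove_component <- function(data, decomp, index) {
  if (!is_count(index) || index > decomp$n_components)
    stop("component index out of range")
  m <- concatenate_trials(data)
  if (ncol(m) != ncol(decomp$sources))
    stop("decomposition does not match the data")
  contrib <- decomp$mixing[, index] %o% decomp$sources[index, ]
  out <- list(data = matrix_to_epochs(m - contrib, data), method = "ica",
              selected_indices = index,
              converged = decomp$converged, n_iter = decomp$n_iter)
  class(out) <- "cleaning_result"
  out
}

#' Clean a corrupted dataset with FastICA component subtraction
#'
#' Trials are concatenated, decomposed with symmetric tanh FastICA, and the
#' single component whose topography best matches the known simulated
#' artifact pattern is subtracted.
#'
#' @param corrupted an `epoched_data`.
#' @param known_topography unit-norm artifact topography.
#' @param n_components number of independent components (60 at full scale).
#' @param seed RNG seed for the ICA initialization.
#' @param tol,max_iter FastICA convergence parameters.
#' @return a `cleaning_result` with `selected_cos` (absolute cosine of the
#'   removed component's topography with the known one) and the
#'   convergence flag.
#' @export
clean_dataset_ica <- function(corrupted, known_topography,
                              n_components = 60, seed = 1L,
                              tol = 1e-6, max_iter = 1000) {
  m <- concatenate_trials(corrupted)
  dec <- fastica_decompose(m, min(n_components, nrow(m)), seed, tol,
                           max_iter)
  idx <- select_artifact_component(dec, known_topography)
  res <- remove_component(corrupted, dec, idx)
  a <- dec$mixing[, idx]
  res$selected_cos <- abs(sum(unit(a) * known_topography))
  res
}
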