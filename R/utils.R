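#' @keywords internal
"_PACKAGE"

# package-local cache (lead fields, wavelet interpolant)
.tmseegsim_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' All randomness in grid runs flows from one master seed through this
#' derivation, so any single cell can be re-executed in isolation.  The
#' result is always a positive integer below 2^31.
#'
#' @param master integer master seed.
#' @param index integer stream index (>= 0); distinct indices give distinct
#'   streams for any fixed master seed.
#' @return a positive integer seed.
#' @export
derive_seed <- function(master, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483629 # largest prime < 2^31
  s <- (abs(as.double(master)) %% m)
  s <- (s * 48271 + as.double(index) * 7919 + 1) %% m
  as.integer(s + 1)
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

vnorm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  x / n
}

# Legendre polynomials P_n(u) and derivatives P_n'(u), n = 1..nmax,
# vectorized over u.  Returns list of two length(u) x nmax matrices.
# Recursions: n P_n = (2n-1) u P_{n-1} - (n-1) P_{n-2};
#             P_n' = P_{n-2}' + (2n-1) P_{n-1}  (stable at |u| = 1).
legendre_table <- function(u, nmax) {
  u <- as.numeric(u)
  P <- matrix(0, length(u), nmax)
  dP <- matrix(0, length(u), nmax)
  Pm2 <- rep(1, length(u))  # P_0
  Pm1 <- u                  # P_1
  dPm2 <- rep(0, length(u))
  dPm1 <- rep(1, length(u))
  P[, 1] <- Pm1
  dP[, 1] <- dPm1
  if (nmax >= 2) {
    for (n in 2:nmax) {
      Pn <- ((2 * n - 1) * u * Pm1 - (n - 1) * Pm2) / n
      dPn <- dPm2 + (2 * n - 1) * Pm1
      P[, n] <- Pn
      dP[, n] <- dPn
      Pm2 <- Pm1; Pm1 <- Pn
      dPm2 <- dPm1; dPm1 <- dPn
    }
  }
  list(P = P, dP = dP)
}

# quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  th <- ga * (seq_len(n) - 1)
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

# short fingerprint of an R object (no external hash dependency)
config_fingerprint <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 15)), collapse = ";")
  v <- utf8ToInt(s)
  a <- 5381
  for (k in v) a <- (a * 33 + k) %% 2147483647
  sprintf("%08x", as.integer(a))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)
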