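# Independent oracles, kept free of the package's implementation paths.

# Closed-form potential of a dipole p at r0 inside a homogeneous conducting
# sphere (radius R, conductivity sigma, insulated boundary), evaluated at a
# surface point given by the unit vector e_unit.  Derived by analytically
# summing the Legendre series (2n+1)/n * (infinite-medium coefficients):
#   2 V_inf  +  (1/(bR)) [ p.bhat (R/d - 1)
#                          + p.(e - u bhat) t (1+g) / (g (1 - t u + g)) ]
# with t = b/R, g = d/R, u = e.bhat.
oracle_hom_sphere_potential <- function(p, r0, e_unit, R, sigma = 1) {
  re <- e_unit * R
  b <- sqrt(sum(r0^2))
  bhat <- r0 / b
  d <- sqrt(sum((re - r0)^2))
  u <- sum(e_unit * bhat)
  tt <- b / R
  g <- d / R
  q <- 1 - tt * u + g
  (1 / (4 * pi * sigma)) * (
    2 * sum(p * (re - r0)) / d^3 +
      (1 / (b * R)) * (sum(p * bhat) * (R / d - 1) +
                         sum(p * (e_unit - u * bhat)) * tt * (1 + g) /
                           (g * q)))
}

# brute-force Eq.-14 relative error: explicit loops, no vectorized reuse
oracle_relative_error <- function(cleaned, truth, window) {
  keep <- which(truth$times >= window[1] & truth$times <= window[2])
  ntr <- dim(truth$data)[3]
  nch <- dim(truth$data)[1]
  res <- numeric(ntr)
  for (i in seq_len(ntr)) {
    num <- 0
    den <- 0
    for (ch in seq_len(nch)) {
      for (tix in keep) {
        num <- num + (cleaned$data[ch, tix, i] - truth$data[ch, tix, i])^2
        den <- den + truth$data[ch, tix, i]^2
      }
    }
    res[i] <- num / den
  }
  mean(res)
}

# textbook balanced two-way ANOVA sums of squares from cell means
oracle_anova_ss <- function(y, A, B) {
  A <- as.factor(A); B <- as.factor(B)
  grand <- mean(y)
  a <- nlevels(A); b <- nlevels(B)
  n <- length(y) / (a * b)
  ybar_a <- tapply(y, A, mean)
  ybar_b <- tapply(y, B, mean)
  ybar_ab <- tapply(y, list(A, B), mean)
  ss_a <- b * n * sum((ybar_a - grand)^2)
  ss_b <- a * n * sum((ybar_b - grand)^2)
  ss_ab <- n * sum((ybar_ab - outer(ybar_a, rep(1, b)) -
                      outer(rep(1, a), ybar_b) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab,
       ss_e = ss_tot - ss_a - ss_b - ss_ab, ss_tot = ss_tot,
       df = c(a - 1, b - 1, (a - 1) * (b - 1), a * b * (n - 1)))
}

# mean relative error helper used across simulation tests
mean_re <- function(cleaned, truth, window = c(0, 50))
  relative_error(cleaned, truth, window)$mean_re
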