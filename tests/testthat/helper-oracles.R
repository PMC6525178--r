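# Independent oracles: no calls into the package's own closed forms.

# spherical-cap volume and full-sphere volume, written out directly
oracle_cap <- function(h, d) pi * ((d / 2) * h^2 - h^3 / 3)
oracle_v0 <- function(d) pi * d^3 / 6

# retained volume via the two published piecewise branches (t >= d / t < d),
# scalar x; deliberately not the unified min/max form used in the package
oracle_retained <- function(x, t, d) {
  if (t >= d) {
    if (x <= d) oracle_cap(x, d)
    else if (x <= t) oracle_v0(d)
    else oracle_v0(d) - oracle_cap(x - t, d)
  } else {
    if (x <= t) oracle_cap(x, d)
    else if (x <= d) oracle_cap(x, d) - oracle_cap(x - t, d)
    else oracle_v0(d) - oracle_cap(x - t, d)
  }
}

# retention probability by adaptive numeric quadrature of the piecewise oracle
oracle_retention_p <- function(t, d, c) {
  x1 <- d / 2 * (1 - sqrt(1 - c^2))
  x2 <- t + d / 2 * (1 + sqrt(1 - c^2))
  f <- Vectorize(function(x) oracle_retained(x, t, d))
  val <- stats::integrate(f, x1, x2, rel.tol = 1e-12,
                          subdivisions = 2000L)$value
  val / ((x2 - x1) * oracle_v0(d))
}

# pmf of the number of retained signals by exhaustive enumeration of all
# 2^N retention outcomes; never touches the binomial formula or dbinom
oracle_count_pmf <- function(N, p) {
  if (N == 0L) return(1)
  outcomes <- as.matrix(expand.grid(rep(list(c(0L, 1L)), N)))
  w <- apply(outcomes, 1L, function(o) prod(ifelse(o == 1L, p, 1 - p)))
  k <- rowSums(outcomes)
  vapply(0:N, function(n) sum(w[k == n]), numeric(1L))
}
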