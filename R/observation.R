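#' Distribution of the observed per-nucleus signal count
#'
#' Under uniform signal placement, each of the `N` true copies survives
#' sectioning independently with the retention probability `p`, so the
#' observed count is Binomial(N, p). The same law governs the target gene
#' and the control probe; only `N` differs.
#'
#' @param N True copy number per nucleus (non-negative integer).
#' @param p Retention probability in (0, 1], typically from
#'   [retention_probability()].
#' @return An object of class `counts_pmf`: list with `support` (0..N),
#'   `prob`, and the parameters `N`, `p`.
#' @examples
#' pmf <- observed_pmf(8, retention_probability(section_spec(2, 3, 0.8)))
#' sum(pmf$prob[pmf$support >= 6]) # chance of a positive call
#' @export
observed_pmf <- function(N, p) {
  stopifnot(length(N) == 1L, length(p) == 1L, is.finite(N), is.finite(p))
  if (N < 0 || N != round(N)) stop("N must be a non-negative integer", call. = FALSE)
  if (p <= 0 || p > 1) stop("p must be in (0, 1]", call. = FALSE)
  support <- 0:N
  structure(list(support = support,
                 prob = stats::dbinom(support, size = N, prob = p),
                 N = as.integer(N), p = p),
            class = "counts_pmf")
}

#' @export
print.counts_pmf <- function(x, ...) {
  law <- if (identical(x$method, "depth_mixture")) "depth mixture" else "Binomial"
  cat(sprintf("counts_pmf: %s (N = %d, p = %.6g)\n", law, x$N, x$p))
  print(stats::setNames(round(x$prob, 6), x$support))
  invisible(x)
}

#' Expected observed copy number
#'
#' Mean of the observed count: `N * p(spec)`. `N` may be non-integer (the
#' mean copy number of a mixed cell population); the full pmf in
#' [observed_pmf()] is the single-clone, integer-`N` case.
#'
#' @param N True copy number (real, >= 0).
#' @param spec A [section_spec()].
#' @return Expected observed copies.
#' @export
expected_observed <- function(N, spec) {
  stopifnot(N >= 0)
  N * retention_probability(spec)
}

#' Expected target/control ratio under sectioning
#'
#' Both probes are thinned by the same retention probability, so the ratio
#' of expected counts equals the true ratio `N_G / N_C` for every section
#' thickness: sectioning biases copy numbers but not the ratio. Note this is
#' a ratio of expectations, not the expectation of per-nucleus ratios.
#'
#' @param N_G True target-gene copies (>= 0).
#' @param N_C True control-probe copies (> 0).
#' @param spec A [section_spec()]; retained for the record, does not affect
#'   the value.
#' @return List with `ratio` and `ratio_of_expectations = TRUE`.
#' @export
expected_ratio <- function(N_G, N_C, spec) {
  stopifnot(N_G >= 0)
  if (N_C <= 0) stop("control copy number N_C must be > 0", call. = FALSE)
  spec <- as_section_spec(spec)
  list(ratio = N_G / N_C, ratio_of_expectations = TRUE,
       t = spec$t, d = spec$d, c = spec$c)
}

#' Sampling distribution of the m-nucleus mean count
#'
#' A slide-level score averages counts over `m` enumerated nuclei. For
#' `m <= exact_max` the distribution of the mean is computed exactly by
#' m-fold convolution of the single-nucleus pmf (support on multiples of
#' 1/m); for larger `m` a normal approximation
#' `N(N p, N p (1 - p) / m)` is used.
#'
#' @param N True copy number (non-negative integer).
#' @param spec A [section_spec()].
#' @param m Number of nuclei enumerated (>= 1).
#' @param exact_max Largest `m` handled by exact convolution (default 30).
#' @return For the exact branch, a list of class `mean_pmf` with `support`
#'   (mean values), `prob`, `mean`, `sd`, `m`, `method = "exact"`. For the
#'   normal branch, the same shape with `support`/`prob` equal to `NULL` and
#'   `method = "normal"`.
#' @export
mean_sampling_distribution <- function(N, spec, m, exact_max = 30) {
  stopifnot(m >= 1, m == round(m))
  p <- retention_probability(spec)
  mu <- N * p
  sdev <- sqrt(N * p * (1 - p) / m)
  if (m <= exact_max) {
    single <- stats::dbinom(0:N, size = N, prob = p)
    prob <- single
    for (i in seq_len(m - 1)) {
      # distribution of the sum after adding one more nucleus
      prob <- as.vector(stats::convolve(prob, rev(single), type = "open"))
    }
    prob[prob < 0] <- 0          # FFT round-off
    prob <- prob / sum(prob)
    structure(list(support = (0:(N * m)) / m, prob = prob,
                   mean = mu, sd = sdev, m = m, N = N, p = p,
                   method = "exact"),
              class = "mean_pmf")
  } else {
    structure(list(support = NULL, prob = NULL,
                   mean = mu, sd = sdev, m = m, N = N, p = p,
                   method = "normal"),
              class = "mean_pmf")
  }
}

#' Observed-count probability curves across section thicknesses
#'
#' Long-format table of `P(n)` for each section specification, the data
#' behind per-thickness probability curves and bubble plots of observed
#' copy number versus thickness.
#'
#' @param N True copy number (non-negative integer).
#' @param specs A list of [section_spec()] objects.
#' @return A data.frame with columns `thickness_um`, `diameter_um`,
#'   `threshold_c`, `n_observed`, `probability`.
#' @examples
#' specs <- lapply(c(3, 4), function(t) section_spec(t, 3, 0.8))
#' head(probability_plot_data(13, specs))
#' @export
probability_plot_data <- function(N, specs) {
  if (length(specs) == 0L) stop("need at least one section_spec", call. = FALSE)
  rows <- lapply(specs, function(sp) {
    sp <- as_section_spec(sp)
    pmf <- observed_pmf(N, retention_probability(sp))
    data.frame(thickness_um = sp$t, diameter_um = sp$d, threshold_c = sp$c,
               n_observed = pmf$support, probability = pmf$prob)
  })
  do.call(rbind, rows)
}

#' Exact per-nucleus count distribution under the geometric model
#'
#' The binomial in [observed_pmf()] uses the population-average retention
#' probability; the count for a nucleus at depth `x` is actually
#' Binomial(N, V(x)/V0), so across enumerated nuclei the observed count
#' follows the depth mixture
#' `P(n) = mean over x in [x1, x2] of Binom(n | N, V(x)/V0)`,
#' evaluated here by adaptive quadrature. It shares the binomial's mean
#' `N p` but is overdispersed; it is the exact law the Monte Carlo
#' simulator converges to.
#'
#' @param N True copy number (non-negative integer).
#' @param spec A [section_spec()].
#' @param rel_tol Quadrature relative tolerance (default 1e-10).
#' @return A `counts_pmf`-shaped list with `support`, `prob`, `N`, `p`
#'   (the average retention probability, for reference) and
#'   `method = "depth_mixture"`.
#' @export
depth_mixture_pmf <- function(N, spec, rel_tol = 1e-10) {
  spec <- as_section_spec(spec)
  if (N < 0 || N != round(N)) stop("N must be a non-negative integer", call. = FALSE)
  w <- enumeration_window(spec)
  v0 <- sphere_volume(spec$d)
  prob <- vapply(0:N, function(n) {
    stats::integrate(function(x) {
      stats::dbinom(n, N, .retained(x, spec$t, spec$d) / v0)
    }, w[["x1"]], w[["x2"]], rel.tol = rel_tol,
    subdivisions = 500L)$value / (w[["x2"]] - w[["x1"]])
  }, numeric(1L))
  structure(list(support = 0:N, prob = prob, N = as.integer(N),
                 p = retention_probability(spec), method = "depth_mixture"),
            class = "counts_pmf")
}
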