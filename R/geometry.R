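#' Section specification
#'
#' Bundles the three governing parameters of the sectioning model: the
#' microtome section thickness `t`, the nuclear diameter `d` (nuclei are
#' modeled as spheres), and the enumeration threshold `c` -- the minimum
#' fraction of the full image diameter at which a human scorer counts a
#' nucleus. The derived acceptable image diameter is `d_e = c * d`.
#'
#' @param t Section thickness, micrometers (> 0).
#' @param d Nuclear diameter, micrometers (> 0).
#' @param c Enumeration threshold, dimensionless fraction in (0, 1].
#'   Default 0.8, the conventional scoring threshold.
#' @return An object of class `section_spec`: a list with elements
#'   `t`, `d`, `c` and `d_e`.
#' @examples
#' section_spec(t = 4, d = 3, c = 0.8)
#' @export
section_spec <- function(t, d, c = 0.8) {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t),
            is.numeric(d), length(d) == 1L, is.finite(d),
            is.numeric(c), length(c) == 1L, is.finite(c))
  if (t <= 0) stop("section thickness t must be > 0", call. = FALSE)
  if (d <= 0) stop("nuclear diameter d must be > 0", call. = FALSE)
  if (c <= 0 || c > 1) stop("enumeration threshold c must be in (0, 1]", call. = FALSE)
  structure(list(t = t, d = d, c = c, d_e = c * d), class = "section_spec")
}

#' @export
print.section_spec <- function(x, ...) {
  cat(sprintf("section_spec: t = %g um, d = %g um, c = %g (d_e = %g um)\n",
              x$t, x$d, x$c, x$d_e))
  invisible(x)
}

as_section_spec <- function(spec) {
  if (inherits(spec, "section_spec")) return(spec)
  stop("expected a 'section_spec' object; see section_spec()", call. = FALSE)
}

#' Volume of a sphere
#'
#' @param d Diameter, micrometers (>= 0). Vectorized.
#' @return Volume pi * d^3 / 6, cubic micrometers.
#' @examples
#' sphere_volume(3) # 4.5 * pi
#' @export
sphere_volume <- function(d) {
  if (any(d < 0)) stop("diameter must be non-negative", call. = FALSE)
  pi * d^3 / 6
}

#' Volume of a spherical cap
#'
#' Volume of the cap of height `x` cut from a sphere of diameter `d`:
#' `pi * ((d/2) x^2 - x^3 / 3)`. At `x = d` it recovers the full sphere.
#'
#' @param x Cap height, micrometers, in `[0, d]`. Vectorized.
#' @param d Sphere diameter, micrometers.
#' @return Cap volume, cubic micrometers.
#' @examples
#' cap_volume(1.5, 3) # half of sphere_volume(3)
#' @export
cap_volume <- function(x, d) {
  if (any(x < 0 | x > d)) stop("cap height must lie in [0, d]", call. = FALSE)
  pi * ((d / 2) * x^2 - x^3 / 3)
}

# cap volume without domain checks, for internal vectorized use
.cap <- function(x, d) pi * ((d / 2) * x^2 - x^3 / 3)

# antiderivative of .cap in x: integral_0^x cap(u, d) du
.cap_int <- function(x, d) pi * ((d / 6) * x^3 - x^4 / 12)

#' In-slab volume of a truncated nucleus
#'
#' Volume of the part of a spherical nucleus retained inside the section
#' slab, as a function of the depth `x` of the nucleus's lowest point below
#' the slab's top face. The slab occupies depths `[0, t]`; a nucleus
#' intersects it for `x` in `[0, t + d]`. The piecewise closed forms for
#' `t >= d` and `t < d` unify to
#' `cap(min(x, d)) - cap(max(x - t, 0))`.
#'
#' @param x Depth of the nucleus's lowest point, micrometers, in
#'   `[0, t + d]`. Vectorized.
#' @param spec A [section_spec()] (only `t` and `d` are used).
#' @return Retained volume, cubic micrometers.
#' @examples
#' sp <- section_spec(4, 3)
#' retained_volume(3.5, sp) == sphere_volume(3) # fully inside
#' @export
retained_volume <- function(x, spec) {
  spec <- as_section_spec(spec)
  t <- spec$t; d <- spec$d
  if (any(x < 0 | x > t + d)) {
    stop("depth x must lie in [0, t + d]", call. = FALSE)
  }
  .retained(x, t, d)
}

.retained <- function(x, t, d) {
  .cap(pmin(x, d), d) - .cap(pmax(x - t, 0), d)
}

#' Enumeration window of depths
#'
#' The range of depths `x` over which the nucleus's largest in-slab
#' cross-section has diameter at least `c * d`, i.e. the nucleus would be
#' counted by an observer applying threshold `c`:
#' `x1 = (d/2)(1 - sqrt(1 - c^2))`, `x2 = t + (d/2)(1 + sqrt(1 - c^2))`.
#'
#' @param spec A [section_spec()].
#' @return Named numeric vector `c(x1, x2)`, micrometers.
#' @examples
#' enumeration_window(section_spec(4, 3, 0.8)) # c(0.6, 6.4)
#' @export
enumeration_window <- function(spec) {
  spec <- as_section_spec(spec)
  s <- sqrt(1 - spec$c^2)
  c(x1 = spec$d / 2 * (1 - s), x2 = spec$t + spec$d / 2 * (1 + s))
}

# integral_0^x of .retained(u, t, d) du, valid for x in [0, t + d]
.retained_int <- function(x, t, d) {
  v0 <- pi * d^3 / 6
  .cap_int(pmin(x, d), d) + v0 * pmax(x - d, 0) -
    .cap_int(pmin(pmax(x - t, 0), d), d)
}

#' Mean retained nuclear volume over the enumeration window
#'
#' Average of [retained_volume()] over depths uniform on the enumeration
#' window `[x1, x2]`. Computed exactly: the integrand is piecewise cubic, so
#' the antiderivative is piecewise quartic and the integral is evaluated in
#' closed form (no numeric quadrature).
#'
#' @param spec A [section_spec()].
#' @return Mean retained volume, cubic micrometers.
#' @export
mean_retained_volume <- function(spec) {
  spec <- as_section_spec(spec)
  w <- enumeration_window(spec)
  (.retained_int(w[["x2"]], spec$t, spec$d) -
     .retained_int(w[["x1"]], spec$t, spec$d)) / (w[["x2"]] - w[["x1"]])
}

#' Signal-retention probability
#'
#' The probability that a signal uniformly distributed within an enumerated
#' nucleus survives sectioning: `p = mean_retained_volume / sphere_volume`.
#' Strictly increasing in `t`; tends to 1 as `t` grows.
#'
#' @param spec A [section_spec()].
#' @return Retention probability `p` in (0, 1].
#' @examples
#' retention_probability(section_spec(4, 3, 0.8)) # ~0.682
#' @export
retention_probability <- function(spec) {
  spec <- as_section_spec(spec)
  mean_retained_volume(spec) / sphere_volume(spec$d)
}

#' Retention summary for a section specification
#'
#' @param spec A [section_spec()].
#' @return A list with `mean_volume` (um^3), `full_volume` (um^3), `p`, and
#'   the window bounds `x1`, `x2` (um).
#' @export
retention_summary <- function(spec) {
  spec <- as_section_spec(spec)
  w <- enumeration_window(spec)
  mv <- mean_retained_volume(spec)
  v0 <- sphere_volume(spec$d)
  list(t = spec$t, d = spec$d, c = spec$c,
       x1 = w[["x1"]], x2 = w[["x2"]],
       mean_volume = mv, full_volume = v0, p = mv / v0)
}

#' Image-diameter fraction of a truncated nucleus
#'
#' Largest in-slab cross-section diameter divided by the full diameter `d`,
#' as a function of depth `x`. Equals 1 when the sphere's center lies inside
#' the slab; otherwise it is the chord diameter at the nearer slab face.
#' Equals exactly `c` at the enumeration-window edges `x1` and `x2`.
#'
#' @param x Depth of the nucleus's lowest point, micrometers, in
#'   `[0, t + d]`. Vectorized.
#' @param spec A [section_spec()] (only `t` and `d` are used).
#' @return Fraction of `d` in `[0, 1]`.
#' @export
image_diameter_fraction <- function(x, spec) {
  spec <- as_section_spec(spec)
  t <- spec$t; d <- spec$d
  if (any(x < 0 | x > t + d)) {
    stop("depth x must lie in [0, t + d]", call. = FALSE)
  }
  .image_fraction(x, t, d)
}

.image_fraction <- function(x, t, d) {
  r <- d / 2
  ctr <- x - r                   # depth of sphere center below top face
  # distance from center to nearest in-slab plane; 0 if center inside slab
  dist <- pmax(pmax(-ctr, ctr - t), 0)
  frac <- numeric(length(x))
  inside <- dist < r
  frac[inside] <- sqrt(r^2 - dist[inside]^2) / r
  frac
}

#' Fraction of intersecting nuclei with a full-diameter image
#'
#' Of all nuclei intersecting the slab (lowest-point depth uniform on
#' `[0, t + d]`), the fraction whose image shows the full diameter `d`,
#' i.e. whose center lies inside the slab: `t / (t + d)`.
#'
#' @param t Section thickness, um. @param d Nuclear diameter, um.
#' @return Fraction in (0, 1).
#' @examples
#' fraction_full_diameter(2, 3) # 0.40
#' @export
fraction_full_diameter <- function(t, d) {
  stopifnot(t > 0, d > 0)
  t / (t + d)
}

#' Fraction of intersecting nuclei with image diameter at least c*d
#'
#' Enumeration-window length over the intersecting range:
#' `(t + d * sqrt(1 - c^2)) / (t + d)`.
#'
#' @param t Section thickness, um. @param d Nuclear diameter, um.
#' @param c Enumeration threshold in (0, 1].
#' @return Fraction in (0, 1].
#' @examples
#' fraction_image_at_least(2, 3, 0.8) # 0.76
#' @export
fraction_image_at_least <- function(t, d, c) {
  stopifnot(t > 0, d > 0, c > 0, c <= 1)
  (t + d * sqrt(1 - c^2)) / (t + d)
}

#' Fraction retaining full volume among enumerated nuclei
#'
#' Among nuclei whose image diameter is at least `c * d`, the fraction whose
#' whole sphere lies inside the slab: `max(t - d, 0) / (x2 - x1)`. Zero
#' whenever `t <= d` -- on sections thinner than the nucleus, no counted
#' nucleus is complete.
#'
#' @inheritParams fraction_image_at_least
#' @return Fraction in `[0, 1)`.
#' @examples
#' fraction_full_volume_given_image(8, 3, 0.8) # ~0.51
#' @export
fraction_full_volume_given_image <- function(t, d, c) {
  stopifnot(t > 0, d > 0, c > 0, c <= 1)
  max(t - d, 0) / (t + d * sqrt(1 - c^2))
}

#' Fraction retaining at least a volume fraction v among enumerated nuclei
#'
#' Among nuclei with image diameter >= `c * d`, the fraction whose retained
#' volume is at least `v` times the full sphere volume. Solves
#' `cap_volume(h, d) = (1 - v) * V0` for the cap height `h` by bracketed
#' root finding (tolerance 1e-10); the qualifying depth range has length
#' `max(t - d + 2 h, 0)`. Reduces to [fraction_full_volume_given_image()]
#' at `v = 1`.
#'
#' @inheritParams fraction_image_at_least
#' @param v Required volume fraction in (0, 1].
#' @return Fraction in `[0, 1]`.
#' @export
fraction_volume_at_least_given_image <- function(t, d, c, v) {
  stopifnot(t > 0, d > 0, c > 0, c <= 1, v > 0, v <= 1)
  if (v == 1) return(fraction_full_volume_given_image(t, d, c))
  v0 <- sphere_volume(d)
  f <- function(h) .cap(h, d) - (1 - v) * v0
  # f(0) = -(1-v)V0 < 0 and f(d) = v*V0 > 0, so a root always brackets
  if (f(d) <= 0) stop("no cap-height root in (0, d]", call. = FALSE)
  h <- stats::uniroot(f, c(0, d), tol = 1e-10)$root
  w <- enumeration_window(section_spec(t, d, c))
  min(max(t - d + 2 * h, 0) / (w[["x2"]] - w[["x1"]]), 1)
}
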