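test_that("sphere and cap volumes match the closed forms and reject bad input", {
  expect_equal(sphere_volume(3), 4.5 * pi)
  expect_equal(sphere_volume(2), 4 / 3 * pi)
  expect_identical(sphere_volume(0), 0)
  expect_error(sphere_volume(-1), "non-negative")

  expect_equal(cap_volume(0, 3), 0)
  expect_equal(cap_volume(3, 3), 4.5 * pi)       # cap height d = full sphere
  expect_equal(cap_volume(1.5, 3), 2.25 * pi)    # half sphere by symmetry
  expect_error(cap_volume(-0.1, 3), "\\[0, d\\]")
  expect_error(cap_volume(3.1, 3), "\\[0, d\\]")
})

test_that("retained volume matches the piecewise branches, is symmetric and continuous", {
  sp <- section_spec(4, 3)
  expect_equal(retained_volume(1, sp), pi * (1.5 - 1 / 3))
  expect_equal(retained_volume(3.5, sp), 4.5 * pi)   # fully inside the slab
  sp2 <- section_spec(2, 3)
  expect_equal(retained_volume(2.5, sp2), (2.5^2 * 1.5 - 2.5^3 / 3) * pi -
                 (0.5^2 * 1.5 - 0.5^3 / 3) * pi)     # cap(2.5) - cap(0.5)
  expect_error(retained_volume(-0.01, sp), "t \\+ d")
  expect_error(retained_volume(7.01, sp), "t \\+ d")

  # agreement with the published two-branch piecewise oracle, both regimes
  for (pars in list(c(t = 4, d = 3), c(t = 2, d = 3), c(t = 3, d = 3))) {
    sp_i <- section_spec(pars[["t"]], pars[["d"]])
    xs <- seq(0, pars[["t"]] + pars[["d"]], length.out = 101L)
    expect_equal(retained_volume(xs, sp_i),
                 vapply(xs, oracle_retained, numeric(1L),
                        t = pars[["t"]], d = pars[["d"]]))
    # reflection symmetry V(x) = V((t+d) - x)
    expect_equal(retained_volume(xs, sp_i),
                 rev(retained_volume(rev(pars[["t"]] + pars[["d"]] - xs), sp_i)))
  }

  # continuity across the t = d regime switch
  xs <- seq(0, 5.9, length.out = 40L)
  lo <- retained_volume(xs, section_spec(3 - 1e-9, 3))
  hi <- retained_volume(xs, section_spec(3 + 1e-9, 3))
  expect_equal(lo, hi, tolerance = 1e-7)
})

test_that("enumeration window matches its closed form and widens as c decreases", {
  expect_equal(unname(enumeration_window(section_spec(4, 3, 0.8))), c(0.6, 6.4))
  expect_equal(unname(enumeration_window(section_spec(4, 3, 1))), c(1.5, 5.5))
  w <- enumeration_window(section_spec(4, 3, 1e-9))
  expect_equal(unname(w), c(0, 7), tolerance = 1e-8)
  widths <- vapply(c(1, 0.9, 0.8, 0.7), function(cc) {
    diff(enumeration_window(section_spec(4, 3, cc)))
  }, numeric(1L))
  expect_true(all(diff(widths) > 0))
})

test_that("closed-form mean retained volume agrees with adaptive quadrature to 1e-10", {
  expect_equal(mean_retained_volume(section_spec(4, 3, 0.8)), 3.06993 * pi,
               tolerance = 1e-5)
  expect_equal(mean_retained_volume(section_spec(2, 3, 0.8)), 2.31726 * pi,
               tolerance = 1e-5)
  expect_equal(mean_retained_volume(section_spec(1e4, 3, 0.8)), sphere_volume(3),
               tolerance = 1e-3)
  for (t in 1:10) for (d in c(2, 3, 4)) for (cc in c(0.7, 0.8, 0.9, 1)) {
    sp <- section_spec(t, d, cc)
    p_closed <- retention_probability(sp)
    p_quad <- oracle_retention_p(t, d, cc)
    expect_equal(p_closed, p_quad, tolerance = 1e-10,
                 label = sprintf("p(t=%g,d=%g,c=%g)", t, d, cc))
  }
})

test_that("retention probability reproduces reference values and is monotone", {
  expect_equal(retention_probability(section_spec(4, 3, 0.8)), 0.682206,
               tolerance = 2e-6)
  expect_equal(retention_probability(section_spec(2, 3, 0.8)), 0.514947,
               tolerance = 1e-6)
  expect_equal(retention_probability(section_spec(6, 3, 0.8)), 0.763693,
               tolerance = 1e-6)
  expect_equal(retention_probability(section_spec(1e4, 3, 0.8)), 1,
               tolerance = 1e-3)
  p_t <- vapply(seq(1, 12, by = 0.5), function(t) {
    retention_probability(section_spec(t, 3, 0.8))
  }, numeric(1L))
  expect_true(all(diff(p_t) > 0))
  p_c <- vapply(c(0.5, 0.7, 0.8, 0.9, 1), function(cc) {
    retention_probability(section_spec(4, 3, cc))
  }, numeric(1L))
  expect_true(all(diff(p_c) >= 0))
})

test_that("image-diameter fraction hits the window edges at exactly c", {
  sp <- section_spec(4, 3, 0.8)
  expect_equal(image_diameter_fraction(0.6, sp), 0.8)
  expect_equal(image_diameter_fraction(7, sp), 0)      # tangent nucleus
  expect_equal(image_diameter_fraction(3.5, sp), 1)    # center inside slab
  for (cc in c(0.6, 0.8, 0.95, 1)) {
    sp_i <- section_spec(4, 3, cc)
    w <- enumeration_window(sp_i)
    expect_equal(image_diameter_fraction(w[["x1"]], sp_i), cc, tolerance = 1e-12)
    expect_equal(image_diameter_fraction(w[["x2"]], sp_i), cc, tolerance = 1e-12)
  }
  expect_error(image_diameter_fraction(7.5, sp), "t \\+ d")
})

test_that("complete-nucleus fractions reproduce the published percentage ranges", {
  expect_equal(fraction_full_diameter(2, 3), 0.40)
  expect_equal(fraction_full_diameter(8, 3), 8 / 11)            # ~73%
  expect_equal(fraction_image_at_least(2, 3, 0.8), 0.76)
  expect_equal(fraction_image_at_least(8, 3, 0.8), 9.8 / 11)    # ~89%
  expect_equal(fraction_full_volume_given_image(8, 3, 0.8), 5 / 9.8,
               tolerance = 1e-12)                               # ~51%
  expect_equal(fraction_full_volume_given_image(2, 3, 0.8), 0)
  expect_equal(fraction_full_volume_given_image(3, 3, 0.9), 0)  # t = d boundary
  expect_equal(fraction_image_at_least(2, 3, 1e-12), 1, tolerance = 1e-9)
  # t -> infinity limits
  expect_equal(fraction_full_diameter(1e6, 3), 1, tolerance = 1e-5)
})

test_that("volume-at-least fraction solves the cap equation and reduces correctly", {
  expect_equal(fraction_volume_at_least_given_image(8, 3, 0.8, 1),
               fraction_full_volume_given_image(8, 3, 0.8))
  # independent check: the v = 0.8 cap height satisfies cap(h) = 0.2 V0
  got <- fraction_volume_at_least_given_image(8, 3, 0.8, 0.8)
  h <- uniroot(function(h) oracle_cap(h, 3) - 0.2 * oracle_v0(3),
               c(0, 1.5), tol = 1e-12)$root
  expect_equal(h, 0.8614222, tolerance = 1e-6)
  expect_equal(got, (8 - 3 + 2 * h) / 9.8, tolerance = 1e-9)
  expect_equal(got, 0.686, tolerance = 1e-3)
  # any retained volume qualifies as v -> 0+
  expect_equal(fraction_volume_at_least_given_image(8, 3, 0.8, 1e-9), 1)
})

test_that("section_spec validates its invariants", {
  sp <- section_spec(4, 3, 0.8)
  expect_s3_class(sp, "section_spec")
  expect_equal(sp$d_e, 2.4)
  expect_error(section_spec(0, 3), "t must be")
  expect_error(section_spec(4, -1), "d must be")
  expect_error(section_spec(4, 3, 0), "c must be")
  expect_error(section_spec(4, 3, 1.1), "c must be")
})
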