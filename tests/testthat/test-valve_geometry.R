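# Parametric annulus construction, cohort sampling and annular metrics.

test_that("cohort sampling respects intervals, size and seed", {
  spec <- cohort_spec(n = 100, seed = 1)
  cohort <- sample_cohort(spec)
  expect_equal(nrow(cohort), 100)
  rng <- default_ranges()
  for (nm in names(rng)) {
    expect_true(all(cohort[[nm]] >= rng[[nm]][1]),
                info = paste(nm, "below lower bound"))
    expect_true(all(cohort[[nm]] <= rng[[nm]][2]),
                info = paste(nm, "above upper bound"))
  }
  # determinism: same seed, bitwise-identical draws
  expect_identical(sample_cohort(cohort_spec(n = 50, seed = 7)),
                   sample_cohort(cohort_spec(n = 50, seed = 7)))
  expect_false(identical(sample_cohort(cohort_spec(n = 50, seed = 7)),
                         sample_cohort(cohort_spec(n = 50, seed = 8))))
  # empty cohort
  expect_equal(nrow(sample_cohort(cohort_spec(n = 0))), 0)
  # broad containment sweep
  big <- sample_cohort(cohort_spec(n = 5000, seed = 3))
  expect_true(all(big$delta_area >= 5 & big$delta_area <= 20))
  expect_true(all(big$d_ap >= 20.1 & big$d_ap <= 40.2))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(n = -1), "non-negative")
  bad <- default_ranges(); bad$d_ap <- c(40, 20)
  expect_error(cohort_spec(ranges = bad), "lower must be < upper")
  expect_error(valve_params(0, 25, 160, 13, 15, 16, 10), "length")
  expect_error(valve_params(30, 25, 200, 13, 15, 16, 10), "phi_bend")
  expect_error(valve_params(30, 25, 160, 13, 15, 16, 100), "delta_area")
})

test_that("a planar circular annulus reproduces closed forms", {
  p <- valve_params(20, 20, 180, 10, 10, 10, 10)
  m <- annulus_metrics(build_annulus(p, 96))
  expect_equal(m$circumference, 2 * pi * 10, tolerance = 0.005)
  expect_equal(m$area, pi * 100, tolerance = 0.005)
  expect_equal(m$bending_angle, 180, tolerance = 1e-6)
  expect_equal(m$d_ap, 20, tolerance = 1e-9)
  expect_equal(m$d_sl, 20, tolerance = 1e-9)
  expect_lt(m$height, 1e-9)
})

test_that("ellipse landmark diameters come from the landmark pairs", {
  p <- valve_params(4, 2, 180, 1, 1, 1, 0)
  m <- annulus_metrics(build_annulus(p, 64))
  expect_equal(m$d_ap, 4, tolerance = 1e-9)
  expect_equal(m$d_sl, 2, tolerance = 1e-9)
})

test_that("a bent annulus measures its bending angle and gains height", {
  p <- valve_params(30, 25, 150, 13, 15, 16, 10)
  m <- annulus_metrics(build_annulus(p, 96))
  expect_equal(m$bending_angle, 150, tolerance = 0.5)
  expect_gt(m$height, 0)
})

test_that("geometry round-trip holds across random pseudo-patients", {
  cohort <- sample_cohort(cohort_spec(n = 100, seed = 11))
  for (i in seq_len(nrow(cohort))) {
    p <- row_params(cohort[i, ])
    m <- annulus_metrics(build_annulus(p, 96))
    expect_lt(abs(m$d_ap - p$d_ap) / p$d_ap, 0.005)
    expect_lt(abs(m$d_sl - p$d_sl) / p$d_sl, 0.005)
    expect_lt(abs(m$bending_angle - p$phi_bend), 0.5)
  }
})

test_that("uniform scaling scales circumference linearly and area quadratically", {
  p1 <- valve_params(30, 25, 160, 13, 15, 16, 10)
  p2 <- valve_params(60, 50, 160, 26, 30, 32, 10)
  m1 <- annulus_metrics(build_annulus(p1, 96))
  m2 <- annulus_metrics(build_annulus(p2, 96))
  expect_equal(m2$circumference / m1$circumference, 2, tolerance = 0.005)
  expect_equal(m2$area / m1$area, 4, tolerance = 0.005)
})

test_that("annulus construction preconditions are enforced", {
  p <- valve_params(30, 25, 160, 13, 15, 16, 10)
  expect_error(build_annulus(p, 8), ">= 32")
  expect_error(build_annulus(p, 34), "multiple of 4")
  expect_error(annulus_metrics(structure(list(points = matrix(0, 10, 3)),
                                         class = "annulus_curve")),
               "at least 32")
})

test_that("cyclic change uses the max-min convention per metric", {
  p <- valve_params(30, 25, 160, 13, 15, 16, 10)
  m <- annulus_metrics(build_annulus(p, 64))
  expect_equal(unname(cycle_change(m, m)), rep(0, 4))

  # direct formula: area 100 -> 84 gives 16%
  m1 <- m; m2 <- m
  m1$area <- 100; m2$area <- 84
  expect_equal(unname(cycle_change(m1, m2)["area"]), 16)
  # ordering does not matter (max/min, not temporal)
  expect_equal(cycle_change(m1, m2), cycle_change(m2, m1))
  expect_true(all(cycle_change(m2, m1) >= 0))
})

test_that("lofted leaflets partition into three labeled sectors", {
  p <- valve_params(30, 25, 160, 13, 15, 16, 10)
  mesh <- loft_leaflets(build_annulus(p, 48), p, n_radial = 3)
  expect_setequal(levels(mesh$label), c("septal", "anterior", "posterior"))
  expect_true(all(table(mesh$label) > 0))
  expect_false(anyNA(mesh$label))
  # annulus vertices reproduce the generating curve
  curve <- build_annulus(p, 48)
  expect_lt(max(abs(mesh$vertices[mesh$annulus_idx, ] - curve$points)), 1e-6)
  # free edge is a single closed inner loop of the annulus length
  expect_length(mesh$free_edge_idx, 48)
})

test_that("leaflet depth matches heights and scales with them", {
  p <- valve_params(30, 25, 160, 8, 9, 10, 10)
  mesh <- loft_leaflets(build_annulus(p, 48), p, n_radial = 3)
  expect_equal(leaflet_depth(mesh, "septal"), 8, tolerance = 0.02)
  expect_equal(leaflet_depth(mesh, "anterior"), 9, tolerance = 0.02)
  expect_equal(leaflet_depth(mesh, "posterior"), 10, tolerance = 0.02)

  p2 <- valve_params(30, 25, 160, 16, 18, 20, 10)
  mesh2 <- loft_leaflets(build_annulus(p2, 48), p2, n_radial = 3)
  for (lf in c("septal", "anterior", "posterior")) {
    expect_equal(leaflet_depth(mesh2, lf) / leaflet_depth(mesh, lf), 2,
                 tolerance = 0.02)
  }
})

test_that("degenerate leaflet heights are rejected", {
  expect_error(valve_params(30, 25, 160, 13, 15, 0, 10), "length")
  expect_error(valve_params(30, 25, 160, 13, 15, -1, 10), "length")
})
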