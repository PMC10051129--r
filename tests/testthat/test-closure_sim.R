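# Quasi-static closure: load-free identity, contraction tracking,
# convergence contract, contact behavior.

test_that("zero pressure and zero contraction leave the valve unchanged", {
  v <- small_valve(delta_area = 0)
  cfg <- simulation_config(pressure = 0, delta_area = 0, n_steps = 2,
                           max_iter = 500)
  st <- simulate_closure(v$mesh, cfg)
  expect_lt(max(abs(st$positions - v$mesh$vertices)), 1e-6)
  expect_true(st$converged)
  expect_equal(st$achieved_area_change, 0, tolerance = 1e-9)
  expect_false(any(st$contact))
})

test_that("prescribed annular area change is achieved across the range", {
  v <- small_valve()
  for (target in c(5, 12, 20)) {
    cfg <- fast_config(delta_area = target)
    st <- simulate_closure(v$mesh, cfg)
    expect_lt(abs(st$achieved_area_change - target), 0.5)
  }
})

test_that("hitting the iteration cap reports non-convergence in-state", {
  v <- small_valve()
  cfg <- simulation_config(delta_area = 10, n_steps = 2, tol = 1e-12,
                           max_iter = 30)
  st <- simulate_closure(v$mesh, cfg)
  expect_false(st$converged)
  expect_s3_class(st, "closed_valve")
  expect_equal(nrow(st$positions), nrow(v$mesh$vertices))
  expect_gt(st$residual, 1e-12)
})

test_that("closure simulation is deterministic", {
  v <- small_valve()
  cfg <- fast_config(delta_area = 10)
  s1 <- simulate_closure(v$mesh, cfg)
  s2 <- simulate_closure(v$mesh, cfg)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$step_log, s2$step_log)
})

test_that("the residual decreases through the load ramp log", {
  v <- small_valve()
  st <- simulate_closure(v$mesh, fast_config(delta_area = 10))
  expect_equal(nrow(st$step_log), 5)
  expect_true(all(is.finite(st$step_log$residual)))
})

test_that("an open reference valve has no coapted vertices", {
  v <- small_valve()
  flags <- coaptation_map(as_state(v$mesh$vertices), v$mesh, 0.4)
  expect_false(any(flags))
  expect_error(coaptation_map(as_state(v$mesh$vertices), v$mesh, 0),
               "thickness")
})

test_that("two parallel sheets within the threshold are fully flagged", {
  # two flat triangulated strips separated by thickness/2
  nx <- 8; ny <- 4
  g <- expand.grid(x = seq(0, 7, length.out = nx),
                   y = seq(0, 3, length.out = ny))
  sheet <- as.matrix(cbind(g, z = 0))
  quads <- function(offset) {
    ij <- expand.grid(i = 1:(nx - 1), j = 1:(ny - 1))
    a <- (ij$j - 1) * nx + ij$i
    rbind(cbind(a, a + 1, a + nx), cbind(a + 1, a + nx + 1, a + nx)) + offset
  }
  verts <- rbind(sheet, sheet + matrix(c(0, 0, 0.2), nx * ny, 3, byrow = TRUE))
  tris <- rbind(quads(0), quads(nx * ny))
  mesh <- structure(list(vertices = verts, triangles = tris,
                         label = factor(rep(c("anterior", "septal"),
                                            each = nrow(tris) / 2),
                                        levels = c("septal", "anterior",
                                                   "posterior")),
                         annulus_idx = integer(0), free_edge_idx = integer(0),
                         papillary = rbind(c(0, 0, -5), c(1, 0, -5))),
                    class = "leaflet_mesh")
  flags <- coaptation_map(as_state(verts), mesh, 0.4)
  expect_true(all(flags))
  # same fixture mirrored in x: the flag set maps under the vertex mirror
  verts_m <- verts
  verts_m[, 1] <- 7 - verts_m[, 1]
  mesh_m <- mesh; mesh_m$vertices <- verts_m
  flags_m <- coaptation_map(as_state(verts_m), mesh_m, 0.4)
  expect_identical(flags, flags_m)
  # pulling the sheets apart clears every flag
  verts2 <- verts
  verts2[seq_len(nx * ny) + nx * ny, 3] <- 5
  flags2 <- coaptation_map(as_state(verts2), mesh, 0.4)
  expect_false(any(flags2))
})

test_that("contact keeps inter-leaflet penetration within bounds", {
  # strong closure drives leaflets together; penalty contact must keep
  # penetration below 10% of the contact thickness
  p <- valve_params(26, 22, 165, 14, 15, 16, 18)
  mesh <- loft_leaflets(build_annulus(p, 32), p, n_radial = 2)
  cfg <- fast_config(delta_area = 18)
  st <- simulate_closure(mesh, cfg)
  expect_lte(penetration_depth(st, mesh, cfg$contact_thickness),
             0.1 * cfg$contact_thickness)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(k_membrane = 0), "stiffnesses")
  expect_error(simulation_config(tol = 0), "tol")
  expect_error(simulation_config(delta_area = 120), "delta_area")
  expect_error(simulation_config(contact_thickness = -1), "contact_thickness")
})
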