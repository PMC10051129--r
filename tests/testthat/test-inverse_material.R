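# Inverse estimation of stiffness parameters from point clouds.

test_that("forward-difference gradients match analytic derivatives", {
  g <- forward_difference_gradient(function(p) sum(p^2), c(1, 2), 1e-6)
  expect_equal(g, c(2, 4), tolerance = 1e-4)
  expect_error(forward_difference_gradient(function(p) sum(p^2), c(1, 2), 0),
               "step_fraction")
  expect_error(forward_difference_gradient(function(p) sum(p^2), c(0, 2),
                                           1e-6), "nonzero")
  # forward difference of an asymmetric function: error is O(h)
  g2 <- forward_difference_gradient(function(p) exp(p[1]), 1, 1e-8)
  expect_equal(g2, exp(1), tolerance = 1e-6)
})

test_that("point-to-surface distances are exact on a flat patch", {
  # unit-square patch of two triangles; points above it at height d
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  F <- rbind(c(1, 2, 3), c(1, 3, 4))
  set.seed(6)
  P <- cbind(runif(60, 0.1, 0.9), runif(60, 0.1, 0.9), 0)
  expect_equal(tvsim:::point_surface_distance(P, V, F), rep(0, 60))
  d <- 0.37
  P2 <- P; P2[, 3] <- d
  expect_equal(tvsim:::point_surface_distance(P2, V, F), rep(d, 60),
               tolerance = 1e-12)
  # translating the cloud by d normal to the patch adds N * d to the sum
  expect_equal(sum(tvsim:::point_surface_distance(P2, V, F)) -
                 sum(tvsim:::point_surface_distance(P, V, F)),
               60 * d, tolerance = 1e-9)
  # off-edge points use the clamped edge projection
  P3 <- rbind(c(2, 0.5, 0), c(-1, 0.5, 1))
  expect_equal(tvsim:::point_surface_distance(P3, V, F),
               c(1, sqrt(2)), tolerance = 1e-12)
})

test_that("a self-generated target has (near) zero residual", {
  fx <- inverse_fixture()
  st <- simulate_closure(fx$mesh, tvsim:::apply_material(fx$config,
                                                         material_params(1, 2)))
  expect_true(st$converged)
  r <- point_cloud_residual(material_params(1, 2), fx$mesh, st$positions,
                            fx$config)
  expect_lt(r, 1e-6)
})

test_that("forward non-convergence raises an error naming the parameters", {
  fx <- inverse_fixture()
  cfg <- fx$config
  cfg$max_iter <- 5L
  cfg$tol <- 1e-12
  st <- simulate_closure(fx$mesh, cfg)
  expect_error(point_cloud_residual(material_params(1, 2), fx$mesh,
                                    st$positions, cfg),
               "k_membrane = 1")
  expect_error(point_cloud_residual(material_params(1, 2), fx$mesh,
                                    matrix(0, 10, 3), fx$config),
               "at least 50")
})

test_that("material parameters are recovered from a synthetic target", {
  fx <- inverse_fixture()
  truth <- material_params(1.0, 2.0)
  st <- simulate_closure(fx$mesh, tvsim:::apply_material(fx$config, truth))
  fit <- fit_material(fx$mesh, st$positions, material_params(2.0, 4.0),
                      fx$config, fd_step = 0.01, tol = 2e-5, patience = 5,
                      max_iter = 80, warm_start = st$positions)
  expect_lt(abs(fit$params["k_membrane"] - 1), 0.05)
  expect_lt(abs(fit$params["k_chordae"] - 2) / 2, 0.05)
  expect_true(all(diff(fit$trajectory) <= 1e-9))
})

test_that("recovery degrades gracefully under segmentation-scale noise", {
  fx <- inverse_fixture()
  set.seed(77)
  errs <- c()
  for (run in 1:5) {
    truth <- material_params(runif(1, 0.8, 3), runif(1, 0.8, 3))
    cfg_t <- fx$config
    cfg_t$k_membrane <- unname(truth["k_membrane"])
    cfg_t$k_chordae <- unname(truth["k_chordae"])
    st <- simulate_closure(fx$mesh, cfg_t)
    cloud <- surface_cloud(st$positions, fx$mesh$triangles)
    noisy <- cloud + matrix(rnorm(length(cloud), sd = 0.1), nrow(cloud), 3)
    init <- material_params(truth["k_membrane"] * 1.6,
                            truth["k_chordae"] * 0.7)
    fit <- fit_material(fx$mesh, noisy, init, fx$config,
                        warm_start = st$positions)
    errs <- c(errs, 100 * abs(fit$params - unclass(truth)) / unclass(truth))
  }
  expect_lt(median(errs), 15)
})

test_that("starting at the truth terminates immediately at the floor", {
  fx <- inverse_fixture()
  truth <- material_params(1.0, 2.0)
  st <- simulate_closure(fx$mesh, tvsim:::apply_material(fx$config, truth))
  fit <- fit_material(fx$mesh, st$positions, truth, fx$config,
                      warm_start = st$positions)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 3)
  expect_lt(fit$residual, 1e-4)
})

test_that("an unreachable target hits the cap without faking convergence", {
  fx <- inverse_fixture()
  truth <- material_params(1.0, 2.0)
  st <- simulate_closure(fx$mesh, tvsim:::apply_material(fx$config, truth))
  target <- st$positions + matrix(c(0, 0, 8), nrow(st$positions), 3,
                                  byrow = TRUE)
  fit <- fit_material(fx$mesh, target, material_params(1.5, 3),
                      fx$config, max_iter = 2, warm_start = st$positions)
  expect_false(fit$converged)
  expect_true(all(diff(fit$trajectory) <= 1e-9))
  expect_gt(fit$residual, 100)
})

test_that("the residual landscape probe flags flat valleys", {
  fx <- inverse_fixture()
  st <- simulate_closure(fx$mesh, tvsim:::apply_material(fx$config,
                                                         material_params(1, 2)))
  ls <- residual_landscape(fx$mesh, st$positions, fx$config,
                           k_membrane_grid = c(0.8, 1.0, 1.25),
                           k_chordae_grid = c(1.6, 2.0, 2.5))
  expect_equal(dim(ls$residuals), c(3, 3))
  expect_true(all(is.finite(ls$residuals)))
  # the grid minimum sits at the truth
  expect_equal(unname(which(ls$residuals == min(ls$residuals),
                            arr.ind = TRUE)[1, ]), c(2, 2))

  # a far-off target varies hardly at all across the grid: flat warning
  far <- st$positions + matrix(c(0, 0, 500), nrow(st$positions), 3,
                               byrow = TRUE)
  expect_warning(residual_landscape(fx$mesh, far, fx$config,
                                    k_membrane_grid = c(0.9, 1, 1.1),
                                    k_chordae_grid = c(1.8, 2, 2.2)),
                 "identifiable")
})
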