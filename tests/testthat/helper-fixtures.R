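# Shared fixtures, built in code.

# Flat annular ring mesh in the z = 0 plane: outer radius R fully covered
# by triangles down to inner radius r (the "orifice"). Doubles as a
# leaflet_mesh and, with positions = vertices, as a closed-valve state for
# the analytic orifice-area checks.
ring_mesh <- function(R = 10, r = 5, n = 96) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  outer_ring <- cbind(R * cos(t), R * sin(t), 0)
  inner_ring <- cbind(r * cos(t), r * sin(t), 0)
  verts <- rbind(outer_ring, inner_ring)
  i <- seq_len(n)
  ip <- c(2:n, 1)
  tris <- rbind(cbind(i, ip, n + i),
                cbind(ip, n + ip, n + i))
  structure(list(
    vertices = verts,
    triangles = tris,
    label = factor(rep("anterior", nrow(tris)),
                   levels = c("septal", "anterior", "posterior")),
    annulus_idx = seq_len(n), free_edge_idx = n + seq_len(n),
    is_annulus = c(rep(TRUE, n), rep(FALSE, n)),
    is_free_edge = c(rep(FALSE, n), rep(TRUE, n)),
    papillary = rbind(c(3, 0, -8), c(-3, 0, -8)),
    sector = factor(rep("anterior", n),
                    levels = c("septal", "anterior", "posterior")),
    n_points = n, n_radial = 1L), class = "leaflet_mesh")
}

as_state <- function(positions) {
  structure(list(positions = positions, converged = TRUE, residual = 0,
                 achieved_area_change = 0, contact = NULL),
            class = "closed_valve")
}

# small valve + config for fast closure tests
small_valve <- function(delta_area = 10, heights = c(13, 15, 16)) {
  p <- valve_params(30, 25, 160, heights[1], heights[2], heights[3],
                    delta_area)
  list(params = p, mesh = loft_leaflets(build_annulus(p, 32), p, n_radial = 2))
}

fast_config <- function(delta_area = 10, ...) {
  simulation_config(n_steps = 5, tol = 2e-4, max_iter = 6000,
                    delta_area = delta_area, ...)
}

# inverse-analysis demonstration fixture: pressurized tension-field
# closure with bending regularization (single smooth equilibrium branch)
inverse_fixture <- function() {
  p <- valve_params(30, 25, 160, 12, 13, 13, 0)
  mesh <- loft_leaflets(build_annulus(p, 32), p, n_radial = 2)
  config <- simulation_config(pressure = 4, delta_area = 0, n_steps = 3,
                              tol = 1e-4, max_iter = 10000, k_bend = 0.5,
                              tension_field = TRUE)
  list(mesh = mesh, config = config)
}

# dense point cloud on a mesh surface: vertices plus four barycentric
# samples per face (a segmentation-like sampling of the surface)
surface_cloud <- function(positions, triangles) {
  W <- rbind(c(1, 1, 1) / 3, c(.6, .2, .2), c(.2, .6, .2), c(.2, .2, .6))
  out <- positions
  for (w in seq_len(nrow(W))) {
    out <- rbind(out,
                 W[w, 1] * positions[triangles[, 1], , drop = FALSE] +
                   W[w, 2] * positions[triangles[, 2], , drop = FALSE] +
                   W[w, 3] * positions[triangles[, 3], , drop = FALSE])
  }
  out
}

# brute-force 1D two-cluster oracle: best split of sorted data by WCSS
brute_force_split <- function(x) {
  xs <- sort(x)
  n <- length(x)
  best <- Inf; best_k <- 1L
  for (k in 1:(n - 1)) {
    left <- xs[1:k]; right <- xs[(k + 1):n]
    w <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (w < best) { best <- w; best_k <- k }
  }
  list(wcss = best, threshold = (xs[best_k] + xs[best_k + 1]) / 2)
}

# synthetic cohort from known standardized logistic coefficients
logistic_cohort <- function(n, beta, intercept = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n,
              dimnames = list(NULL, tv_feature_names()[seq_along(beta)]))
  pr <- stats::plogis(intercept + drop(X %*% beta))
  df <- as.data.frame(X)
  df$tr_severe <- stats::rbinom(n, 1, pr)
  df
}
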