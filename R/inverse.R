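# Inverse estimation of tissue stiffness parameters: iteratively match
# the simulated closed-valve surface to a target point cloud (in practice
# a manual echocardiogram segmentation; here usually synthetic) by
# gradient descent on a projected-distance residual with forward-
# difference gradients, in log-parameter space.

#' Material parameter set for inverse fitting
#'
#' @param k_membrane Membrane edge stiffness (N/mm).
#' @param k_chordae Chordae stiffness (N/mm).
#' @return Object of class `material_params` (named numeric vector).
#' @export
material_params <- function(k_membrane, k_chordae) {
  if (k_membrane <= 0 || k_chordae <= 0)
    stop("material parameters must be strictly positive")
  structure(c(k_membrane = unname(k_membrane), k_chordae = unname(k_chordae)),
            class = "material_params")
}

apply_material <- function(config, params) {
  km <- unname(params["k_membrane"])
  kc <- unname(params["k_chordae"])
  if (!is.finite(km) || !is.finite(kc))
    stop("material parameters must carry k_membrane and k_chordae values")
  config$k_membrane <- km
  config$k_chordae <- kc
  config
}

#' Point-cloud residual of a forward closure simulation
#'
#' Runs the closure simulation with the given material parameters and
#' returns the total projected distance: the sum over target points of
#' the distance to the closest point on the simulated closed surface
#' (orthogonal point-to-triangle projection).
#'
#' @param params A [material_params()] vector.
#' @param ref_mesh Reference (open) [loft_leaflets()] mesh.
#' @param target Point cloud matrix (N x 3, mm) sampled from the closed
#'   valve surface; at least 50 points.
#' @param config Base [simulation_config()]; its stiffness entries are
#'   overridden by `params`.
#' @param return_distances Also return the per-point distances and the
#'   closed-valve state.
#' @param init_positions Optional warm-start positions passed through to
#'   [simulate_closure()] (parameter continuation).
#' @return Residual in mm (sum of distances), or a list with `residual`,
#'   `distances` and `state` when `return_distances = TRUE`. Forward
#'   non-convergence raises an error that names the parameters tried.
#' @export
point_cloud_residual <- function(params, ref_mesh, target, config,
                                 return_distances = FALSE,
                                 init_positions = NULL) {
  target <- as.matrix(target)
  if (nrow(target) < 50) stop("target point cloud needs at least 50 points")
  if (any(!is.finite(target))) stop("target point cloud has non-finite points")
  state <- simulate_closure(ref_mesh, apply_material(config, params),
                            init_positions = init_positions)
  if (!state$converged)
    stop(sprintf(paste0("forward simulation did not converge at ",
                        "k_membrane = %.4g, k_chordae = %.4g ",
                        "(residual %.3g N)"),
                 params["k_membrane"], params["k_chordae"], state$residual))
  d <- point_surface_distance(target, state$positions, ref_mesh$triangles)
  if (return_distances)
    list(residual = sum(d), distances = d, state = state)
  else sum(d)
}

#' Forward-difference gradient
#'
#' `g_i = (f(p + h_i e_i) - f(p)) / h_i` with `h_i = step_fraction * p_i`.
#'
#' @param objective Function of a numeric parameter vector.
#' @param params Numeric parameter vector (nonzero entries).
#' @param step_fraction Relative step size per parameter (> 0).
#' @param f0 Optional pre-computed `objective(params)`.
#' @return Numeric gradient vector.
#' @export
#' @examples
#' forward_difference_gradient(function(p) sum(p^2), c(1, 2), 1e-6)
forward_difference_gradient <- function(objective, params,
                                        step_fraction = 1e-3, f0 = NULL) {
  if (any(step_fraction <= 0)) stop("step_fraction must be > 0")
  if (any(params == 0)) stop("relative steps need nonzero parameters")
  if (is.null(f0)) f0 <- objective(params)
  h <- rep_len(step_fraction, length(params)) * abs(params)
  vapply(seq_along(params), function(i) {
    pi <- params
    pi[i] <- pi[i] + h[i]
    (objective(pi) - f0) / h[i]
  }, numeric(1))
}

#' Fit material parameters to a target point cloud
#'
#' Backtracking gradient descent in log-parameter space on the
#' point-cloud residual, with forward-difference gradients (absolute
#' steps of `fd_step` log units) and an Armijo acceptance rule. Stops
#' when the relative residual change stays below `tol` for `patience`
#' consecutive accepted iterations, when the residual falls below
#' `resid_floor`, or at the iteration cap (reported as non-converged,
#' with the best parameters so far).
#'
#' @param ref_mesh Reference (open) [loft_leaflets()] mesh.
#' @param target Target point cloud (N x 3 matrix, mm).
#' @param init Initial [material_params()].
#' @param config Base [simulation_config()].
#' @param max_iter Iteration cap.
#' @param step0 Initial line-search step (log units).
#' @param shrink Backtracking factor.
#' @param armijo Armijo sufficient-decrease constant.
#' @param tol Relative residual-change convergence tolerance.
#' @param patience Consecutive small-change iterations required.
#' @param fd_step Forward-difference step (log units).
#' @param resid_floor Residual (mm) below which the fit stops as converged.
#' @param warm_start Optional vertex positions seeding the first forward
#'   solve — typically the observed (segmented) closed configuration when
#'   it is available as a mesh-compatible state. Forward solves continue
#'   the equilibrium branch of the current iterate either way; seeding
#'   with the observed state keeps the whole fit on the observed branch
#'   of a multi-stable closure.
#' @return Object of class `inverse_fit`: `params` (fitted
#'   [material_params()]), `trajectory` (residual per accepted iterate,
#'   non-increasing), `converged`, `iterations`, `n_evals`,
#'   `final_distances` (per target point, mm).
#' @export
fit_material <- function(ref_mesh, target, init, config,
                         max_iter = 150L, step0 = 0.4, shrink = 0.5,
                         armijo = 1e-4, tol = 1e-4, patience = 3L,
                         fd_step = 0.01, resid_floor = 1e-4,
                         warm_start = NULL) {
  target <- as.matrix(target)
  n_evals <- 0L
  warm <- warm_start   # equilibrium at the current iterate: successive
                       # solves at nearby parameters continue from it
  obj_log <- function(l, update_warm = FALSE) {
    n_evals <<- n_evals + 1L
    res <- point_cloud_residual(structure(exp(l), names = names(init),
                                          class = "material_params"),
                                ref_mesh, target, config,
                                return_distances = TRUE,
                                init_positions = warm)
    last_pos <<- res$state$positions
    if (update_warm) warm <<- res$state$positions
    res$residual
  }
  last_pos <- NULL
  l <- log(unclass(init))
  f0 <- obj_log(l, update_warm = TRUE)
  trajectory <- f0
  small_changes <- 0L
  converged <- FALSE
  iter <- 0L
  max_move <- 0.3       # per-iteration cap on |step| in log units
  g_prev <- NULL; l_prev <- NULL

  # probe the coordinate axes (half-max_move steps) and move to the best
  # improving point, if any; the residual valley can be nearly flat along
  # one parameter, where gradient steps under-resolve the descent
  probe_axes <- function() {
    best_f <- f0; best_l <- NULL; best_pos <- NULL
    for (h in max_move * c(0.5, 0.2, 0.08)) {
      for (i in seq_along(l)) for (s in c(-1, 1)) {
        li <- l; li[i] <- li[i] + s * h
        fi <- obj_log(li)
        if (fi < best_f) { best_f <- fi; best_l <- li; best_pos <- last_pos }
      }
      if (!is.null(best_l)) break   # take the coarsest improving scale
    }
    if (is.null(best_l)) return(FALSE)
    l <<- best_l; f0 <<- best_f; warm <<- best_pos
    trajectory <<- c(trajectory, best_f)
    g_prev <<- NULL; l_prev <<- NULL
    TRUE
  }

  while (iter < max_iter) {
    iter <- iter + 1L
    if (f0 <= resid_floor) { converged <- TRUE; break }
    accepted <- FALSE
    # if the line search fails (gradient under-resolved near the
    # minimum), retry once with a larger differencing step
    for (fd_try in c(fd_step, 4 * fd_step)) {
      g <- vapply(seq_along(l), function(i) {
        li <- l; li[i] <- li[i] + fd_try
        (obj_log(li) - f0) / fd_try
      }, numeric(1))
      gnorm <- sqrt(sum(g^2))
      if (gnorm < 1e-14) break
      # Barzilai-Borwein step length, clamped; plain scaled step at start
      t_step <- if (!is.null(g_prev)) {
        s <- l - l_prev; y <- g - g_prev
        if (sum(s * y) > 0) sum(s * y) / sum(y * y) else step0 / gnorm
      } else step0 / gnorm
      t_step <- min(t_step, max_move / gnorm)
      while (t_step * gnorm >= 1e-4) {
        f1 <- obj_log(l - t_step * g)
        if (f1 <= f0 - armijo * t_step * gnorm^2) { accepted <- TRUE; break }
        t_step <- t_step * shrink
      }
      if (accepted) break
    }
    if (!accepted) {
      # stalled gradient: axis probes, then one cold-restart attempt
      # (fresh load ramp), kept only if it genuinely improves
      if (probe_axes()) { small_changes <- 0L; next }
      warm_save <- warm; warm <- NULL
      f_cold <- obj_log(l, update_warm = TRUE)
      if (f_cold < f0 * (1 - tol)) {
        f0 <- f_cold
        trajectory <- c(trajectory, f0)
        next
      }
      warm <- warm_save
      # no move improves the residual by more than tol relative: a local
      # minimum at the search resolution
      converged <- TRUE
      break
    }
    rel <- (f0 - f1) / max(f0, 1e-300)
    g_prev <- g; l_prev <- l
    l <- l - t_step * g
    f0 <- f1
    warm <- last_pos   # continue the equilibrium branch from the new iterate
    trajectory <- c(trajectory, f0)
    small_changes <- if (rel < tol) small_changes + 1L else 0L
    if (small_changes >= patience) {
      # slow creep: only stop if the axis probes cannot improve either
      if (probe_axes()) { small_changes <- 0L; next }
      converged <- TRUE
      break
    }
  }
  params <- structure(exp(l), names = names(init), class = "material_params")
  final <- point_cloud_residual(params, ref_mesh, target, config,
                                return_distances = TRUE,
                                init_positions = warm)
  structure(list(params = params, trajectory = trajectory,
                 converged = converged, iterations = iter,
                 n_evals = n_evals, residual = final$residual,
                 final_distances = final$distances),
            class = "inverse_fit")
}

#' @export
print.inverse_fit <- function(x, ...) {
  cat(sprintf(paste0("Inverse material fit: %s after %d iterations ",
                     "(%d forward solves)\n  k_membrane %.4g, k_chordae ",
                     "%.4g N/mm; residual %.4g mm\n"),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$n_evals, x$params["k_membrane"],
              x$params["k_chordae"], x$residual))
  invisible(x)
}

#' Residual landscape over a stiffness grid (identifiability probe)
#'
#' Evaluates the point-cloud residual over a 2D grid of (membrane,
#' chordae) stiffness and fits a local quadratic in log-parameters around
#' the grid minimum; a large condition number of the quadratic's Hessian
#' signals a flat valley, i.e. a non-unique solution, and raises a
#' warning.
#'
#' @param ref_mesh,target,config As in [fit_material()].
#' @param k_membrane_grid,k_chordae_grid Grid values (N/mm).
#' @param cond_limit Condition-number threshold for the non-uniqueness
#'   warning.
#' @return List with `residuals` (matrix, membrane x chordae),
#'   `k_membrane_grid`, `k_chordae_grid`, `condition`, `flat` flag.
#' @export
residual_landscape <- function(ref_mesh, target, config,
                               k_membrane_grid, k_chordae_grid,
                               cond_limit = 1e3) {
  R <- outer(seq_along(k_membrane_grid), seq_along(k_chordae_grid),
             Vectorize(function(i, j) {
               point_cloud_residual(material_params(k_membrane_grid[i],
                                                    k_chordae_grid[j]),
                                    ref_mesh, target, config)
             }))
  lm_ <- log(k_membrane_grid); lc_ <- log(k_chordae_grid)
  g <- expand.grid(a = lm_, b = lc_)
  g$r <- as.vector(R)
  qf <- stats::lm(r ~ a + b + I(a^2) + I(b^2) + I(a * b), data = g)
  cf <- stats::coef(qf)
  H <- matrix(c(2 * cf["I(a^2)"], cf["I(a * b)"],
                cf["I(a * b)"], 2 * cf["I(b^2)"]), 2, 2)
  ev <- abs(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  condition <- if (min(ev) < 1e-300) Inf else max(ev) / min(ev)
  # flat if strongly anisotropic, or if curvature explains almost none of
  # the residual scale across the grid (a uniformly flat landscape)
  span2 <- max(diff(range(lm_)), diff(range(lc_)))^2 / 4
  relative_curv <- max(ev) * span2 / max(mean(R), 1e-300)
  flat <- !is.finite(condition) || condition > cond_limit ||
    relative_curv < 1e-3
  if (flat)
    warning("residual landscape has a flat valley (condition number ",
            format(condition, digits = 3),
            "): the material parameters may not be uniquely identifiable")
  list(residuals = R, k_membrane_grid = k_membrane_grid,
       k_chordae_grid = k_chordae_grid, condition = condition, flat = flat)
}
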