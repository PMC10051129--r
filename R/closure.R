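# Quasi-static valve closure: energy minimization of a linear edge-spring
# membrane under transvalvular pressure, with displacement-driven annular
# contraction, unilateral chordae springs to two fixed papillary points,
# and penalty contact between topologically distant vertices. The
# pressure load is the exact gradient of the enclosed-volume potential
# (taken relative to the annular centroid), which makes the whole system
# conservative and lets a quasi-Newton solver reach tight equilibria; at
# interior vertices this load coincides with the usual lumped
# area-weighted-normal pressure force. A deliberately simple structural
# model whose constants are calibration knobs, not physiologic
# measurements.

#' Configure a closure simulation
#'
#' @param pressure Transvalvular pressure (kPa), ramped with load steps.
#' @param k_membrane Edge spring stiffness (N/mm) of the membrane mesh.
#' @param k_chordae Chordae spring stiffness (N/mm); chordae run from each
#'   free-edge vertex to its nearest papillary point and resist elongation
#'   only.
#' @param k_bend Bending regularization stiffness (N/mm): springs between
#'   the opposite vertices of each adjacent triangle pair resist folding
#'   across mesh edges, selecting smooth (non-wrinkled) equilibria; set
#'   to 0 to disable.
#' @param k_contact Penalty contact stiffness (N/mm).
#' @param contact_thickness Contact activation distance (mm); also the
#'   leaflet coaptation thickness used for contact flags.
#' @param damping Viscous damping factor of the damped-relaxation
#'   stabilization bursts used when the quasi-Newton solver stalls
#'   (dimensionless, in (0, 1)).
#' @param n_steps Number of load-ramp steps over which pressure and
#'   annular contraction are applied linearly.
#' @param tol Equilibrium tolerance: maximum nodal residual force (N).
#' @param max_iter Total energy/gradient evaluation budget across the
#'   ramp.
#' @param delta_area Prescribed systolic annular area change (percent of
#'   reference annular area removed by contraction).
#' @param tension_field Treat the membrane springs as tension-only (slack
#'   under compression), the tension-field idealization of a thin
#'   membrane that wrinkles rather than supporting compression; the
#'   bending springs remain bilateral and select a smooth configuration
#'   for slack regions. Off by default; used by the inverse-analysis
#'   demonstration where a single smooth equilibrium branch matters.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(pressure = 4, k_membrane = 1, k_chordae = 2,
                              k_bend = 0.3, k_contact = 10,
                              contact_thickness = 0.4,
                              damping = 0.1, n_steps = 50, tol = 1e-4,
                              max_iter = 20000, delta_area = 0,
                              tension_field = FALSE) {
  if (k_membrane <= 0 || k_chordae <= 0 || k_contact <= 0)
    stop("stiffnesses must be > 0")
  if (k_bend < 0) stop("k_bend must be >= 0")
  if (pressure < 0) stop("pressure must be >= 0")
  if (contact_thickness <= 0) stop("contact_thickness must be > 0")
  if (damping <= 0 || damping >= 1) stop("damping must lie in (0, 1)")
  if (tol <= 0) stop("tol must be > 0")
  if (delta_area < 0 || delta_area >= 100)
    stop("delta_area must lie in [0, 100)")
  structure(list(pressure = pressure, k_membrane = k_membrane,
                 k_chordae = k_chordae, k_bend = k_bend,
                 k_contact = k_contact,
                 contact_thickness = contact_thickness, damping = damping,
                 n_steps = as.integer(n_steps), tol = tol,
                 max_iter = as.integer(max_iter), delta_area = delta_area,
                 tension_field = isTRUE(tension_field)),
            class = "sim_config")
}

# unique undirected edges of a triangle mesh
mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# opposite-vertex pairs across each interior (shared) mesh edge; springs
# between them resist folding, acting as a discrete bending stiffness
tri_bend_pairs <- function(tris) {
  a <- c(tris[, 1], tris[, 2], tris[, 3])
  b <- c(tris[, 2], tris[, 3], tris[, 1])
  o <- c(tris[, 3], tris[, 1], tris[, 2])
  lo <- pmin(a, b); hi <- pmax(a, b)
  ord <- order(lo, hi)
  lo <- lo[ord]; hi <- hi[ord]; o <- o[ord]
  same <- lo[-1] == lo[-length(lo)] & hi[-1] == hi[-length(hi)]
  cbind(o[c(same, FALSE)], o[c(FALSE, same)])
}

# vertex pairs within graph distance <= k (returned as a logical sparse
# adjacency pattern, used to exclude near-neighbors from contact)
graph_near_pairs <- function(n, edges, k = 4) {
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2], seq_len(n)),
                            j = c(edges[, 2], edges[, 1], seq_len(n)),
                            x = 1, dims = c(n, n))
  P <- A
  for (i in seq_len(k - 1)) P <- P %*% A
  P > 0
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Simulate quasi-static valve closure
#'
#' Ramps transvalvular pressure and prescribed annular contraction over
#' `config$n_steps` load steps. Annulus boundary vertices are
#' displacement-driven: they move affinely toward the annular centroid
#' axis so that the projected annular area is reduced by
#' `config$delta_area` percent at full load. At each step the interior is
#' settled to equilibrium by limited-memory quasi-Newton minimization of
#' the total potential energy (membrane springs, unilateral chordae,
#' contact penalty, pressure-volume work), with the contact candidate set
#' refreshed between solves and short damped-relaxation bursts if the
#' minimizer stalls. The run is deterministic for fixed inputs.
#'
#' @param mesh A [loft_leaflets()] mesh (reference, open configuration).
#' @param config A [simulation_config()].
#' @param init_positions Optional vertex positions to continue from: when
#'   given, the load ramp is skipped and the interior is settled directly
#'   at full load starting from this state. Used for warm-started
#'   parameter continuation (e.g. inside the inverse analysis), where
#'   successive solves at nearby parameters should track the same
#'   equilibrium branch.
#' @return An object of class `closed_valve`: `positions` (deformed
#'   vertices, mm), `converged` flag, `residual` (final max nodal force,
#'   N), `achieved_area_change` (percent), `contact` (per-vertex logical),
#'   `step_log` (data frame of residual per ramp step), `iterations`
#'   (energy/gradient evaluations used). Non-convergence is reported
#'   in-state; non-finite forces raise an error naming the ramp step.
#' @export
simulate_closure <- function(mesh, config, init_positions = NULL) {
  stopifnot(inherits(mesh, "leaflet_mesh"), inherits(config, "sim_config"))
  V0 <- mesh$vertices
  n <- nrow(V0)
  tris <- mesh$triangles
  edges <- mesh_edges(tris)
  springs <- edges
  ks <- rep(config$k_membrane, nrow(edges))
  slackable <- rep(isTRUE(config$tension_field), nrow(edges))
  if (config$k_bend > 0) {
    bp <- tri_bend_pairs(tris)
    springs <- rbind(springs, bp)
    ks <- c(ks, rep(config$k_bend, nrow(bp)))
    slackable <- c(slackable, rep(FALSE, nrow(bp)))
  }
  L0 <- sqrt(rowSums((V0[springs[, 2], ] - V0[springs[, 1], ])^2))

  E <- nrow(springs)
  B <- Matrix::sparseMatrix(i = c(springs[, 1], springs[, 2]),
                            j = c(seq_len(E), seq_len(E)),
                            x = c(rep(1, E), rep(-1, E)), dims = c(n, E))
  m <- nrow(tris)
  corner <- lapply(1:3, function(k)
    Matrix::sparseMatrix(i = tris[, k], j = seq_len(m), x = 1,
                         dims = c(n, m)))
  near <- graph_near_pairs(n, edges, k = 4)

  # annular frame and in-frame boundary coordinates (contraction driver)
  ann <- mesh$annulus_idx
  fr <- annulus_frame(V0[ann, , drop = FALSE])
  rel <- sweep(V0[ann, , drop = FALSE], 2, fr$centroid)
  bu <- drop(rel %*% fr$u); bv <- drop(rel %*% fr$v)
  bw <- drop(rel %*% fr$normal)
  area0 <- projected_polygon_area(V0[ann, , drop = FALSE], fr$normal)

  # chordae: each free-edge vertex is tethered to its nearest papillary
  # point (unilateral springs, at rest in the reference state)
  fe <- mesh$free_edge_idx
  dpap <- vapply(seq_len(nrow(mesh$papillary)), function(k) {
    sqrt(rowSums(sweep(V0[fe, , drop = FALSE], 2, mesh$papillary[k, ])^2))
  }, numeric(length(fe)))
  pap_of <- max.col(-dpap)
  pap_pts <- mesh$papillary[pap_of, , drop = FALSE]
  chord_L0 <- dpap[cbind(seq_along(fe), pap_of)]

  p_full <- config$pressure * 1e-3   # kPa -> N/mm^2
  th <- config$contact_thickness
  free <- setdiff(seq_len(n), ann)
  nf <- length(free)
  c0 <- fr$centroid

  evals <- 0L
  c0m <- matrix(c0, m, 3, byrow = TRUE)
  # total potential energy and nodal forces (-gradient); contact pairs fixed
  energy_forces <- function(X, p_now, cp) {
    evals <<- evals + 1L
    d <- X[springs[, 2], , drop = FALSE] - X[springs[, 1], , drop = FALSE]
    len <- sqrt(rowSums(d * d))
    stretch <- len - L0
    if (any(slackable)) stretch[slackable & stretch < 0] <- 0
    En <- 0.5 * sum(ks * stretch^2)
    FF <- as.matrix(B %*% (d * (ks * stretch / pmax(len, 1e-12))))
    if (p_now > 0) {
      a <- X[tris[, 1], , drop = FALSE] - c0m
      b <- X[tris[, 2], , drop = FALSE] - c0m
      cc <- X[tris[, 3], , drop = FALSE] - c0m
      bxc <- cross3(b, cc)
      En <- En - p_now * sum(a * bxc) / 6
      FF <- FF + (p_now / 6) *
        as.matrix(corner[[1]] %*% bxc + corner[[2]] %*% cross3(cc, a) +
                    corner[[3]] %*% cross3(a, b))
    }
    dch <- pap_pts - X[fe, , drop = FALSE]
    lch <- sqrt(rowSums(dch * dch))
    ch_str <- pmax(lch - chord_L0, 0)
    En <- En + 0.5 * config$k_chordae * sum(ch_str^2)
    fch <- dch * (config$k_chordae * ch_str / pmax(lch, 1e-12))
    for (k in 1:3)
      FF[, k] <- FF[, k] + tabulate2(fe, fch[, k], n)
    if (!is.null(cp) && nrow(cp)) {
      i <- cp[, 1]; j <- cp[, 2]
      dc <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
      lc <- sqrt(rowSums(dc * dc))
      pen <- pmax(th - lc, 0)
      act <- which(pen > 0)
      if (length(act)) {
        En <- En + 0.5 * config$k_contact * sum(pen[act]^2)
        fc <- dc[act, , drop = FALSE] *
          (config$k_contact * pen[act] / pmax(lc[act], 1e-12))
        ii <- i[act]; jj <- j[act]
        for (k in 1:3) {
          FF[, k] <- FF[, k] + tabulate2(ii, fc[, k], n) -
            tabulate2(jj, fc[, k], n)
        }
      }
    }
    list(energy = En, forces = FF)
  }

  refresh_contacts <- function(X) {
    dm <- as.matrix(stats::dist(X))
    cand <- which(dm < 2 * th & upper.tri(dm), arr.ind = TRUE)
    if (nrow(cand)) cand <- cand[!near[cand], , drop = FALSE]
    cand
  }
  max_resid <- function(FF) {
    if (!nf) return(0)
    max(sqrt(rowSums(FF[free, , drop = FALSE]^2)))
  }

  X <- V0
  step_log <- data.frame(step = integer(0), residual = numeric(0))
  resid <- 0
  mass <- 4 * (6 * config$k_membrane + config$k_chordae + config$k_contact)

  settle <- function(X, p_now, step_tol, budget, where) {
    vel <- matrix(0, nf, 3)
    for (outer in 1:6) {
      cp <- refresh_contacts(X)
      ef <- energy_forces(X, p_now, cp)
      if (any(!is.finite(ef$forces)))
        stop("non-finite forces during closure simulation at ", where)
      resid <- max_resid(ef$forces)
      if (resid <= step_tol || evals >= config$max_iter) break
      last <- NULL   # fn/gr cache: L-BFGS evaluates both at the same point
      eval_at <- function(par) {
        if (is.null(last) || !identical(par, last$par)) {
          Xi <- X; Xi[free, ] <- matrix(par, nf, 3)
          last <<- c(energy_forces(Xi, p_now, cp), list(par = par))
          if (!is.finite(last$energy))
            stop("non-finite energy during closure simulation at ", where)
        }
        last
      }
      opt <- stats::optim(
        as.vector(X[free, , drop = FALSE]),
        fn = function(par) eval_at(par)$energy,
        gr = function(par)
          -as.vector(eval_at(par)$forces[free, , drop = FALSE]),
        method = "L-BFGS-B",
        control = list(maxit = budget, pgtol = step_tol / 2, factr = 10))
      Xn <- X; Xn[free, ] <- matrix(opt$par, nf, 3)
      cp2 <- refresh_contacts(Xn)
      ef2 <- energy_forces(Xn, p_now, cp2)
      resid2 <- max_resid(ef2$forces)
      improved <- resid2 < resid
      if (improved) { X <- Xn; resid <- resid2 }
      stable <- identical(dim(cp2), dim(cp)) && all(cp2 == cp)
      if (resid <= step_tol || evals >= config$max_iter) break
      if (!improved || stable) {
        # quasi-Newton stalled (typically contact-set flapping): take a
        # short damped-relaxation burst before retrying, with per-step
        # displacement clamped for stability far from equilibrium
        for (it in 1:30) {
          cp <- refresh_contacts(X)
          FF <- energy_forces(X, p_now, cp)$forces
          if (any(!is.finite(FF)))
            stop("non-finite forces during closure simulation at ", where)
          vel <- (1 - config$damping) * vel + FF[free, , drop = FALSE] / mass
          speed <- sqrt(rowSums(vel^2))
          fast <- speed > 0.2
          if (any(fast)) vel[fast, ] <- vel[fast, , drop = FALSE] * (0.2 / speed[fast])
          X[free, ] <- X[free, , drop = FALSE] + vel
        }
      }
    }
    list(X = X, resid = resid)
  }

  boundary_at <- function(alpha) {
    s <- sqrt(1 - alpha * config$delta_area / 100)
    matrix(fr$centroid, length(ann), 3, byrow = TRUE) +
      outer(s * bu, fr$u) + outer(s * bv, fr$v) + outer(bw, fr$normal)
  }
  if (!is.null(init_positions)) {
    # parameter-continuation mode: settle at full load from the given state
    stopifnot(identical(dim(init_positions), dim(V0)))
    X <- init_positions
    X[ann, ] <- boundary_at(1)
    st <- settle(X, p_full, config$tol, config$max_iter, "continuation solve")
    X <- st$X; resid <- st$resid
    step_log <- data.frame(step = 1L, residual = resid)
  } else {
    per_step <- max(50L, ceiling(config$max_iter / config$n_steps / 2))
    for (step in seq_len(config$n_steps)) {
      alpha <- step / config$n_steps
      X[ann, ] <- boundary_at(alpha)
      step_tol <- if (step == config$n_steps) config$tol else 10 * config$tol
      st <- settle(X, alpha * p_full, step_tol,
                   if (step == config$n_steps) config$max_iter else per_step,
                   paste("ramp step", step))
      X <- st$X; resid <- st$resid
      step_log <- rbind(step_log, data.frame(step = step, residual = resid))
    }
  }

  area1 <- projected_polygon_area(X[ann, , drop = FALSE], fr$normal)
  achieved <- 100 * (area0 - area1) / area0
  state <- structure(list(positions = X, converged = resid <= config$tol,
                          residual = resid, achieved_area_change = achieved,
                          contact = NULL, step_log = step_log,
                          iterations = evals),
                     class = "closed_valve")
  state$contact <- coaptation_map(state, mesh, config$contact_thickness)
  state
}

# scatter-add: sum values v at integer indices idx into a length-n vector
tabulate2 <- function(idx, v, n) {
  out <- numeric(n)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' @export
print.closed_valve <- function(x, ...) {
  cat(sprintf(paste0("Closed valve state: %s (residual %.2e N, %d force ",
                     "evaluations)\n  achieved annular area change: %.2f%%; ",
                     "%d vertices in contact\n"),
              if (x$converged) "converged" else "NOT converged",
              x$residual, x$iterations, x$achieved_area_change,
              sum(x$contact)))
  invisible(x)
}

#' Per-vertex leaflet contact (coaptation) map
#'
#' Flags a vertex as coapted when its distance to a non-neighboring
#' triangle (a triangle containing neither the vertex nor any vertex of
#' its one-ring) of the same or another leaflet is at most `thickness`.
#'
#' @param state A [simulate_closure()] result, or any object with a
#'   `positions` matrix conforming to `mesh`.
#' @param mesh The reference [loft_leaflets()] mesh.
#' @param thickness Contact distance threshold (mm).
#' @return Logical vector, one flag per vertex.
#' @export
coaptation_map <- function(state, mesh, thickness) {
  if (thickness <= 0) stop("thickness must be > 0")
  X <- state$positions
  n <- nrow(X)
  tris <- mesh$triangles
  dm <- point_triangle_distance(X, X, tris)
  # mask triangles topologically adjacent to each vertex
  edges <- mesh_edges(tris)
  adj <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2], seq_len(n)),
                              j = c(edges[, 2], edges[, 1], seq_len(n)),
                              x = 1, dims = c(n, n))
  tri_inc <- Matrix::sparseMatrix(i = rep(seq_len(nrow(tris)), 3),
                                  j = as.vector(tris),
                                  x = 1, dims = c(nrow(tris), n))
  # vertex v near-triangle t iff t contains v or a neighbor of v
  near_tri <- Matrix::t(tri_inc %*% adj > 0)
  dm[as.matrix(near_tri)] <- Inf
  apply(dm, 1, min) <= thickness
}

#' Maximum inter-leaflet penetration depth
#'
#' Largest violation of the contact thickness among topologically distant
#' vertex pairs: `max(thickness - d)` over non-near pairs, floored at 0.
#' Used to verify that penalty contact keeps penetration small.
#'
#' @param state A [simulate_closure()] result.
#' @param mesh The reference [loft_leaflets()] mesh.
#' @param thickness Contact thickness (mm).
#' @return Penetration depth (mm, >= 0).
#' @export
penetration_depth <- function(state, mesh, thickness) {
  X <- state$positions
  n <- nrow(X)
  edges <- mesh_edges(mesh$triangles)
  near <- graph_near_pairs(n, edges, k = 4)
  dm <- as.matrix(stats::dist(X))
  cand <- which(dm < thickness & upper.tri(dm), arr.ind = TRUE)
  if (nrow(cand)) cand <- cand[!near[cand], , drop = FALSE]
  if (!nrow(cand)) return(0)
  max(thickness - dm[cand])
}
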