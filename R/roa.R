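# Regurgitant orifice area by orthographic projection: the closed-valve
# surface is rasterized from a top-down viewpoint and a ring of offset
# viewpoints, and the uncoapted area is the part of the projected annulus
# region not covered by any projected leaflet triangle. The maximum over
# views is the TR severity score.

#' Construct the projection viewpoint set
#'
#' One top-down direction (the annular normal) plus `n_azimuth` offset
#' directions tilted by `theta` degrees from the normal, with azimuths
#' uniformly spaced (45 degrees apart for the default eight).
#'
#' @param frame Annular frame: list with unit vectors `normal`, `u`, `v`
#'   (as produced internally from the annulus loop; see [max_roa()] which
#'   builds it for you).
#' @param theta Tilt angle of the offset viewpoints (degrees, in [0, 90)).
#' @param n_azimuth Number of offset viewpoints.
#' @return An object of class `viewpoint_set`: matrix of unit view
#'   directions (rows; first row is the top-down view) plus the
#'   construction parameters.
#' @export
make_viewpoints <- function(frame, theta = 20, n_azimuth = 8L) {
  if (theta < 0 || theta >= 90) stop("theta must lie in [0, 90) degrees")
  if (n_azimuth < 1) stop("n_azimuth must be >= 1")
  th <- theta * pi / 180
  psi <- seq(0, 2 * pi, length.out = n_azimuth + 1)[-(n_azimuth + 1)]
  dirs <- rbind(frame$normal,
                t(vapply(psi, function(a) {
                  cos(th) * frame$normal +
                    sin(th) * (cos(a) * frame$u + sin(a) * frame$v)
                }, numeric(3))))
  rownames(dirs) <- c("top_down", paste0("offset_", seq_len(n_azimuth)))
  structure(list(directions = dirs, theta = theta,
                 n_azimuth = as.integer(n_azimuth), frame = frame),
            class = "viewpoint_set")
}

# orthonormal basis perpendicular to a unit view direction
view_basis <- function(w) {
  w <- w / sqrt(sum(w^2))
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  rbind(u, v)
}

# mark raster pixels covered by 2D triangles (pixel-center-in-triangle)
rasterize_triangles <- function(tri2d_a, tri2d_b, tri2d_c, x0, y0, res, nx, ny) {
  covered <- matrix(FALSE, nx, ny)
  for (k in seq_len(nrow(tri2d_a))) {
    A <- tri2d_a[k, ]; Bv <- tri2d_b[k, ]; C <- tri2d_c[k, ]
    det <- (Bv[1] - A[1]) * (C[2] - A[2]) - (C[1] - A[1]) * (Bv[2] - A[2])
    if (abs(det) < 1e-12) next
    xs <- range(A[1], Bv[1], C[1]); ys <- range(A[2], Bv[2], C[2])
    i0 <- max(1L, floor((xs[1] - x0) / res - 0.5) + 1L)
    i1 <- min(nx, ceiling((xs[2] - x0) / res + 0.5))
    j0 <- max(1L, floor((ys[1] - y0) / res - 0.5) + 1L)
    j1 <- min(ny, ceiling((ys[2] - y0) / res + 0.5))
    if (i0 > i1 || j0 > j1) next
    px <- x0 + (i0:i1 - 0.5) * res
    py <- y0 + (j0:j1 - 0.5) * res
    gx <- rep(px, times = length(py))
    gy <- rep(py, each = length(px))
    w0 <- ((Bv[1] - A[1]) * (gy - A[2]) - (Bv[2] - A[2]) * (gx - A[1])) / det
    w1 <- ((C[1] - Bv[1]) * (gy - Bv[2]) - (C[2] - Bv[2]) * (gx - Bv[1])) / det
    w2 <- 1 - w0 - w1
    eps <- -1e-9
    hit <- w0 >= eps & w1 >= eps & w2 >= eps
    if (any(hit)) {
      sub <- matrix(hit, length(px), length(py))
      covered[i0:i1, j0:j1] <- covered[i0:i1, j0:j1] | sub
    }
  }
  covered
}

#' Projected regurgitant orifice area for one viewpoint
#'
#' Orthographic projection of the deformed valve along `view`: the area of
#' the region inside the projected annulus loop that is not covered by any
#' projected leaflet triangle, measured by counting raster pixels whose
#' centers are inside the annulus polygon but in no triangle.
#'
#' @param state A [simulate_closure()] result (deformed positions).
#' @param mesh The reference [loft_leaflets()] mesh (connectivity and
#'   annulus ordering).
#' @param view Unit 3-vector view direction.
#' @param resolution Raster resolution (mm per pixel).
#' @return Orifice area in mm^2.
#' @export
orifice_area <- function(state, mesh, view, resolution = 0.05) {
  if (resolution <= 0) stop("resolution must be > 0")
  X <- state$positions
  basis <- view_basis(view)
  P2 <- X %*% t(basis)
  ann2 <- P2[mesh$annulus_idx, , drop = FALSE]
  x0 <- min(ann2[, 1]) - resolution
  y0 <- min(ann2[, 2]) - resolution
  nx <- ceiling((max(ann2[, 1]) + resolution - x0) / resolution)
  ny <- ceiling((max(ann2[, 2]) + resolution - y0) / resolution)
  px <- x0 + (seq_len(nx) - 0.5) * resolution
  py <- y0 + (seq_len(ny) - 0.5) * resolution
  centers <- cbind(rep(px, times = ny), rep(py, each = nx))
  inside <- matrix(mgcv::in.out(ann2, centers), nx, ny)
  if (sum(inside) < 100)
    stop("raster resolution too coarse: the annulus projects to fewer ",
         "than 100 pixels; use a finer (smaller) resolution")
  tris <- mesh$triangles
  covered <- rasterize_triangles(P2[tris[, 1], , drop = FALSE],
                                 P2[tris[, 2], , drop = FALSE],
                                 P2[tris[, 3], , drop = FALSE],
                                 x0, y0, resolution, nx, ny)
  resolution^2 * sum(inside & !covered)
}

#' Maximum regurgitant orifice area over a viewpoint set
#'
#' Computes the projected orifice area for every view direction at a
#' common raster resolution and reports the per-view areas, the maximum
#' (the TR severity score) and the view attaining it.
#'
#' @param state A [simulate_closure()] result.
#' @param mesh The reference [loft_leaflets()] mesh.
#' @param views A [make_viewpoints()] set, or `NULL` to build the default
#'   set (top-down + 8 offsets at 20 degrees) from the deformed annulus.
#' @param resolution Raster resolution (mm per pixel).
#' @return An object of class `roa_result`: `per_view` (named numeric,
#'   mm^2), `max_roa`, `argmax_view` (1 = top-down), `resolution`, `theta`.
#' @export
max_roa <- function(state, mesh, views = NULL, resolution = 0.05) {
  if (is.null(views)) {
    fr <- annulus_frame(state$positions[mesh$annulus_idx, , drop = FALSE])
    views <- make_viewpoints(fr)
  }
  stopifnot(inherits(views, "viewpoint_set"))
  areas <- apply(views$directions, 1, function(d)
    orifice_area(state, mesh, d, resolution))
  structure(list(per_view = areas, max_roa = max(areas),
                 argmax_view = unname(which.max(areas)),
                 resolution = resolution, theta = views$theta),
            class = "roa_result")
}

#' @export
print.roa_result <- function(x, ...) {
  cat(sprintf("Max ROA %.3f mm^2 (view %d of %d, theta %.0f deg, %.3f mm/px)\n",
              x$max_roa, x$argmax_view, length(x$per_view), x$theta,
              x$resolution))
  invisible(x)
}
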