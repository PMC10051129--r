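# Parametric annulus curves and their geometric metrics.
#
# The annulus is built as a planar ellipse (AP semi-axis d_ap/2) folded
# about the AP axis so each half-loop tilts out of plane by
# (180 - phi_bend)/2 degrees; phi_bend = 180 leaves it planar. The SL
# semi-axis is pre-corrected by 1/cos of the fold angle so the landmark
# chord still measures d_sl after folding.

#' Build a parametric annulus curve
#'
#' Realizes the scalar annular measurements as a closed 3D curve: an
#' ellipse with anterior-posterior diameter `d_ap` and septal-lateral
#' diameter `d_sl`, folded about the AP axis by the bending angle.
#' Landmarks for the AP- and SL-axis endpoints are recorded so metrics can
#' be recovered from the curve alone.
#'
#' @param params A [valve_params()] object.
#' @param n_points Number of points on the loop; must be >= 32 and a
#'   multiple of 4 (so the axis landmarks fall exactly on grid points).
#' @return An object of class `annulus_curve`: list with `points`
#'   (`n_points` x 3 matrix, mm; ordered closed loop, counter-clockwise
#'   viewed from the atrial side), `i_ap` and `i_sl` landmark index pairs.
#' @export
#' @examples
#' curve <- build_annulus(valve_params(30, 25, 160, 13, 15, 16, 10))
#' annulus_metrics(curve)
build_annulus <- function(params, n_points = 96L) {
  stopifnot(inherits(params, "valve_params"))
  if (n_points < 32) stop("n_points must be >= 32")
  if (n_points %% 4 != 0) stop("n_points must be a multiple of 4")
  n <- as.integer(n_points)
  a <- params$d_ap / 2
  gamma <- (180 - params$phi_bend) / 2 * pi / 180   # fold angle per half
  b <- (params$d_sl / 2) / cos(gamma)               # pre-correct SL chord
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(t)
  y0 <- b * sin(t)
  # fold both halves toward the ventricular side (-z); SL extremes drop
  pts <- cbind(x = x, y = y0 * cos(gamma), z = -abs(y0) * sin(gamma))
  structure(list(points = pts,
                 i_ap = c(1L, n %/% 2L + 1L),
                 i_sl = c(n %/% 4L + 1L, 3L * (n %/% 4L) + 1L)),
            class = "annulus_curve")
}

# Best-fit plane of a point set: centroid, unit normal (smallest singular
# direction) and an in-plane orthonormal basis.
best_fit_plane <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3], u = sv$v[, 1], v = sv$v[, 2])
}

# Area-weighted (Newell) normal of a closed polygon; orientation follows
# the loop winding, so it is rigid-motion equivariant.
newell_normal <- function(pts) {
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  n <- colSums(cbind(pts[, 2] * nxt[, 3] - pts[, 3] * nxt[, 2],
                     pts[, 3] * nxt[, 1] - pts[, 1] * nxt[, 3],
                     pts[, 1] * nxt[, 2] - pts[, 2] * nxt[, 1])) / 2
  n
}

# Annular reference frame: centroid, unit normal oriented to the atrial
# side (loop winding), and an in-plane basis.
annulus_frame <- function(pts) {
  pl <- best_fit_plane(pts)
  nw <- newell_normal(pts)
  normal <- pl$normal
  if (sum(normal * nw) < 0) normal <- -normal
  u <- pl$u - sum(pl$u * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  list(centroid = pl$centroid, normal = normal, u = u, v = v)
}

# Shoelace area of a 3D polygon projected onto the plane with unit normal n.
projected_polygon_area <- function(pts, normal) {
  abs(sum(newell_normal(pts) * normal))
}

polyline_length <- function(pts, closed = TRUE) {
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  seg <- sqrt(rowSums((nxt - pts)^2))
  if (!closed) seg <- seg[-length(seg)]
  sum(seg)
}

#' Geometric metrics of an annulus curve
#'
#' Measures the quantities used clinically to track annular remodeling:
#' circumference (polyline length of the closed loop), area of the
#' projection onto the best-fit plane, the AP and SL landmark diameters,
#' the bending angle, and the annular height (extent along the best-fit
#' normal). The bending angle is the dihedral angle between the planes
#' fitted to the two half-loops split at the AP landmarks; a planar
#' annulus measures 180 degrees.
#'
#' @param curve An [build_annulus()] result (or any `annulus_curve`).
#' @return An object of class `annulus_metrics`: list with `circumference`
#'   (mm), `area` (mm^2), `d_ap` (mm), `d_sl` (mm), `bending_angle`
#'   (degrees) and `height` (mm).
#' @export
annulus_metrics <- function(curve) {
  stopifnot(inherits(curve, "annulus_curve"))
  pts <- curve$points
  if (nrow(pts) < 32) stop("annulus curve must have at least 32 points")
  circ <- polyline_length(pts)
  if (circ < 1e-9) stop("collapsed annulus curve (zero circumference)")
  fr <- annulus_frame(pts)
  area <- projected_polygon_area(pts, fr$normal)
  d_ap <- sqrt(sum((pts[curve$i_ap[1], ] - pts[curve$i_ap[2], ])^2))
  d_sl <- sqrt(sum((pts[curve$i_sl[1], ] - pts[curve$i_sl[2], ])^2))

  # dihedral between half-loop planes, split at the AP landmarks
  i1 <- curve$i_ap[1]; i2 <- curve$i_ap[2]; n <- nrow(pts)
  half1 <- pts[i1:i2, , drop = FALSE]
  half2 <- pts[c(i2:n, 1:i1), , drop = FALSE]
  n1 <- best_fit_plane(half1)$normal
  n2 <- best_fit_plane(half2)$normal
  if (sum(n1 * fr$normal) < 0) n1 <- -n1
  if (sum(n2 * fr$normal) < 0) n2 <- -n2
  ang <- acos(min(1, max(-1, sum(n1 * n2)))) * 180 / pi
  bending <- 180 - ang

  h <- (pts - matrix(fr$centroid, nrow(pts), 3, byrow = TRUE)) %*% fr$normal
  structure(list(circumference = circ, area = area, d_ap = d_ap,
                 d_sl = d_sl, bending_angle = bending,
                 height = diff(range(h))),
            class = "annulus_metrics")
}

#' @export
print.annulus_metrics <- function(x, ...) {
  cat(sprintf(paste0("Annulus metrics: circumference %.2f mm, area %.2f mm^2,\n",
                     "  d_ap %.2f mm, d_sl %.2f mm, bending %.1f deg, ",
                     "height %.2f mm\n"),
              x$circumference, x$area, x$d_ap, x$d_sl, x$bending_angle,
              x$height))
  invisible(x)
}

#' Cyclic (diastole-to-systole) percent change of annular metrics
#'
#' Percent change of annulus area, circumference and the two landmark
#' diameters over the cardiac cycle, computed as `(max - min) / max * 100`
#' per metric, so the result does not depend on which state is larger.
#'
#' @param diastolic,systolic [annulus_metrics()] of the two cardiac states
#'   of the same valve.
#' @return Named numeric vector of percent changes for `area`,
#'   `circumference`, `d_ap` and `d_sl`.
#' @export
cycle_change <- function(diastolic, systolic) {
  stopifnot(inherits(diastolic, "annulus_metrics"),
            inherits(systolic, "annulus_metrics"))
  pick <- c("area", "circumference", "d_ap", "d_sl")
  a <- unlist(diastolic[pick]); b <- unlist(systolic[pick])
  if (any(a <= 0) || any(b <= 0))
    stop("annular metrics must be positive to compute cyclic change")
  hi <- pmax(a, b); lo <- pmin(a, b)
  (hi - lo) / hi * 100
}
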