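# Lofted three-leaflet surface between the annulus and a constructed
# free edge, with per-triangle leaflet labels and papillary anchor points.

default_sector_spans <- function() c(septal = 120, anterior = 140, posterior = 100)

# Sector of each azimuth (degrees, 0 at the +AP landmark, CCW from the
# atrial side). The anterior sector is centered on the +AP landmark.
sector_of_azimuth <- function(phi_deg, spans = default_sector_spans()) {
  half_ant <- spans[["anterior"]] / 2
  phi <- (phi_deg + half_ant) %% 360   # 0 = anterior sector start
  cuts <- cumsum(c(anterior = spans[["anterior"]], septal = spans[["septal"]],
                   posterior = spans[["posterior"]]))
  out <- character(length(phi))
  out[phi < cuts[1]] <- "anterior"
  out[phi >= cuts[1] & phi < cuts[2]] <- "septal"
  out[phi >= cuts[2]] <- "posterior"
  factor(out, levels = c("septal", "anterior", "posterior"))
}

# circular moving average used to smooth leaflet heights across sector
# boundaries (keeps the sector midlines untouched)
circular_smooth <- function(x, window) {
  if (window <= 0) return(x)
  n <- length(x)
  idx <- outer(seq_len(n), -window:window, function(i, o) ((i + o - 1) %% n) + 1)
  rowMeans(matrix(x[idx], n))
}

#' Loft a three-leaflet surface from an annulus curve
#'
#' Constructs a triangulated leaflet surface between the annulus and a
#' free-edge loop. Each annulus point is mapped to a free-edge point
#' displaced toward the annular centroid axis and toward the ventricular
#' side so that the straight-line annulus-to-free-edge distance equals the
#' local leaflet height; the free-edge radius is floored at 10% of the
#' local annular radius so the reference state keeps an open orifice.
#' Leaflets occupy fixed angular sectors (septal 120, anterior 140,
#' posterior 100 degrees, anterior centered on the +AP landmark). Two
#' papillary anchor points are placed below the annular plane under the
#' anterior-posterior and septal-posterior commissures.
#'
#' @param annulus An [build_annulus()] curve.
#' @param params The generating [valve_params()] (leaflet heights are taken
#'   from here).
#' @param n_radial Number of element layers between annulus and free edge.
#' @param spans Named numeric of sector spans in degrees (must sum to 360).
#' @param inward_fraction Fraction of the leaflet height spent on radial
#'   (inward) displacement of the free edge before the orifice floor binds.
#' @param papillary_depth,papillary_radius Papillary point placement, as
#'   fractions of the mean annular radius (depth below the annular plane,
#'   distance from the centroid axis).
#' @return An object of class `leaflet_mesh`: `vertices` (V x 3 mm),
#'   `triangles` (T x 3 vertex indices), `label` (factor per triangle),
#'   `annulus_idx` / `free_edge_idx` (ordered loops), `is_annulus` /
#'   `is_free_edge` vertex flags, `papillary` (2 x 3 matrix), plus the
#'   generating resolution.
#' @export
#' @examples
#' p <- valve_params(30, 25, 160, 13, 15, 16, 10)
#' mesh <- loft_leaflets(build_annulus(p, 48), p, n_radial = 3)
#' table(mesh$label)
loft_leaflets <- function(annulus, params, n_radial = 4L,
                          spans = default_sector_spans(),
                          inward_fraction = 0.7,
                          papillary_depth = 0.6, papillary_radius = 0.4) {
  stopifnot(inherits(annulus, "annulus_curve"),
            inherits(params, "valve_params"))
  heights <- c(septal = params$h_sept, anterior = params$h_ant,
               posterior = params$h_post)
  if (any(heights <= 0)) stop("leaflet heights must be > 0")
  if (abs(sum(spans) - 360) > 1e-9) stop("sector spans must sum to 360 degrees")
  J <- as.integer(n_radial)
  if (J < 1) stop("n_radial must be >= 1")

  pts <- annulus$points
  n <- nrow(pts)
  fr <- annulus_frame(pts)
  rel <- sweep(pts, 2, fr$centroid)
  pu <- drop(rel %*% fr$u); pv <- drop(rel %*% fr$v)
  r <- sqrt(pu^2 + pv^2)
  if (any(r < 1e-9)) stop("degenerate annulus: point on the centroid axis")
  phi <- (atan2(pv, pu) * 180 / pi) %% 360
  # azimuth origin at the +AP landmark
  phi0 <- phi[annulus$i_ap[1]]
  phi <- (phi - phi0) %% 360
  sector <- sector_of_azimuth(phi, spans)
  h_raw <- heights[as.character(sector)]
  h <- circular_smooth(h_raw, window = max(1L, round(n / 24)))

  # free-edge point: inward by dr, ventricular by dz, with dr^2+dz^2 = h^2
  dr <- pmin(inward_fraction * h, 0.9 * r)
  dz <- sqrt(pmax(h^2 - dr^2, 0))
  e_rad <- cbind(pu / r, pv / r) # radial direction in (u,v) coordinates
  inward3 <- -(outer(e_rad[, 1], fr$u) + outer(e_rad[, 2], fr$v))
  free_edge <- pts + inward3 * dr - outer(dz, fr$normal)

  # lofted layers (ruled surface)
  verts <- matrix(0, (J + 1) * n, 3)
  for (j in 0:J) {
    w <- j / J
    verts[j * n + seq_len(n), ] <- (1 - w) * pts + w * free_edge
  }

  vid <- function(i, j) j * n + ((i - 1L) %% n) + 1L
  i <- rep(seq_len(n), J)
  j <- rep(0:(J - 1), each = n)
  tri1 <- cbind(vid(i, j), vid(i + 1L, j), vid(i, j + 1L))
  tri2 <- cbind(vid(i + 1L, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
  triangles <- rbind(tri1, tri2)
  label <- factor(rep(as.character(sector[i]), 2),
                  levels = levels(sector))

  rbar <- mean(r)
  pap_az <- c((-spans[["anterior"]] / 2) %% 360,                 # ant-post commissure
              (spans[["anterior"]] / 2 + spans[["septal"]]) %% 360) # sept-post commissure
  pap_az <- (pap_az + phi0) * pi / 180
  papillary <- t(vapply(pap_az, function(az) {
    fr$centroid + papillary_radius * rbar * (cos(az) * fr$u + sin(az) * fr$v) -
      papillary_depth * rbar * fr$normal
  }, numeric(3)))

  is_annulus <- is_free_edge <- logical((J + 1) * n)
  is_annulus[seq_len(n)] <- TRUE
  is_free_edge[J * n + seq_len(n)] <- TRUE
  structure(list(vertices = verts, triangles = triangles, label = label,
                 annulus_idx = seq_len(n), free_edge_idx = J * n + seq_len(n),
                 is_annulus = is_annulus, is_free_edge = is_free_edge,
                 papillary = papillary, sector = sector,
                 n_points = n, n_radial = J),
            class = "leaflet_mesh")
}

#' @export
print.leaflet_mesh <- function(x, ...) {
  cat(sprintf("Leaflet mesh: %d vertices, %d triangles (%s)\n",
              nrow(x$vertices), nrow(x$triangles),
              paste(sprintf("%s %d", levels(x$label), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}

#' Annulus-to-free-edge depth at a leaflet's sector midline
#'
#' Straight-line distance from the annulus to the free edge along the
#' lofting column closest to the sector midline; on the generated ruled
#' surface this equals the geodesic annulus-to-free-edge distance.
#'
#' @param mesh A [loft_leaflets()] mesh.
#' @param leaflet One of `"septal"`, `"anterior"`, `"posterior"`.
#' @return Depth in mm.
#' @export
leaflet_depth <- function(mesh, leaflet = c("septal", "anterior", "posterior")) {
  leaflet <- match.arg(leaflet)
  cols <- which(mesh$sector == leaflet)
  # midline column: middle of the circular run of sector columns
  runs <- split(cols, cumsum(c(1, diff(cols) != 1)))
  if (length(runs) > 1 && cols[1] == 1 &&
      cols[length(cols)] == mesh$n_points) {
    # sector wraps around the azimuth origin: join first and last run
    joined <- c(runs[[length(runs)]], runs[[1]])
    runs <- c(list(joined), runs[-c(1, length(runs))])
  }
  run <- runs[[which.max(lengths(runs))]]
  mid <- run[ceiling(length(run) / 2)]
  a <- mesh$vertices[mesh$annulus_idx[mid], ]
  f <- mesh$vertices[mesh$free_edge_idx[mid], ]
  sqrt(sum((a - f)^2))
}
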