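# Point-to-triangle closest distances, vectorized over point x triangle
# pairs. Used for coaptation detection and the inverse-analysis residual.

# Distance from each point to each triangle. P: p x 3, V: vertices,
# F: m x 3 indices. Returns p x m matrix. The unconstrained minimizer in
# barycentric coordinates is used when it falls inside the triangle;
# otherwise the minimum over the three clamped edge projections (the
# boundary of the constraint set) is exact.
point_triangle_distance <- function(P, V, F, chunk = 2e6) {
  p <- nrow(P); m <- nrow(F)
  out <- matrix(0, p, m)
  rows_per_chunk <- max(1L, floor(chunk / m))
  for (start in seq(1L, p, by = rows_per_chunk)) {
    idx <- start:min(p, start + rows_per_chunk - 1L)
    out[idx, ] <- ptd_block(P[idx, , drop = FALSE], V, F)
  }
  out
}

ptd_block <- function(P, V, F) {
  p <- nrow(P); m <- nrow(F)
  A <- V[F[, 1], , drop = FALSE]
  E0 <- V[F[, 2], , drop = FALSE] - A
  E1 <- V[F[, 3], , drop = FALSE] - A
  a <- rowSums(E0 * E0); b <- rowSums(E0 * E1); cc <- rowSums(E1 * E1)
  det <- pmax(a * cc - b * b, 1e-300)

  # expand to all pairs: row-major over points, columns triangles
  ip <- rep(seq_len(p), times = m)
  it <- rep(seq_len(m), each = p)
  D <- P[ip, , drop = FALSE] - A[it, , drop = FALSE]
  d0 <- rowSums(D * E0[it, , drop = FALSE])
  d1 <- rowSums(D * E1[it, , drop = FALSE])
  aa <- a[it]; bb <- b[it]; ccv <- cc[it]; dd <- det[it]

  s <- (ccv * d0 - bb * d1) / dd
  t <- (aa * d1 - bb * d0) / dd
  inside <- s >= 0 & t >= 0 & (s + t) <= 1

  # squared distance helper for a clamped segment origin + u * E
  seg_d2 <- function(proj, len2, D2, dE) {
    u <- pmin(pmax(proj / pmax(len2, 1e-300), 0), 1)
    D2 - 2 * u * dE + u * u * len2
  }
  D2 <- rowSums(D * D)
  # edge A->B (E0), edge A->C (E1)
  e0 <- seg_d2(d0, aa, D2, d0)
  e1 <- seg_d2(d1, ccv, D2, d1)
  # edge B->C: origin B, direction E1-E0
  DB <- D - E0[it, , drop = FALSE]
  E2 <- E1[it, , drop = FALSE] - E0[it, , drop = FALSE]
  dB2 <- rowSums(DB * DB)
  dBe <- rowSums(DB * E2)
  e2 <- seg_d2(dBe, rowSums(E2 * E2), dB2, dBe)
  edge_min <- pmin(e0, e1, e2)

  # interior: distance to the plane
  Q <- D - s * E0[it, , drop = FALSE] - t * E1[it, , drop = FALSE]
  interior <- rowSums(Q * Q)
  d2 <- ifelse(inside, interior, edge_min)
  matrix(sqrt(pmax(d2, 0)), p, m)
}

# Minimum distance from each point to a triangulated surface.
point_surface_distance <- function(P, V, F) {
  dm <- point_triangle_distance(P, V, F)
  apply(dm, 1, min)
}
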