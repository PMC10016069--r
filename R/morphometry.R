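#' Vertex-wise surface area
#'
#' Each triangle of the mid-thickness surface (per-vertex average of white
#' and pial positions) contributes one third of its area to each of its
#' vertices, so vertex areas sum exactly to the total mid-surface area.
#' Degenerate (zero-area) triangles contribute 0.
#'
#' @param surfaces a `surface_pair`.
#' @return numeric per-vertex area (mm^2).
#' @export
vertex_area <- function(surfaces) {
  mid <- (surfaces$white + surfaces$pial) / 2
  tri <- surfaces$triangles
  a <- mid[tri[, 1L], , drop = FALSE]
  b <- mid[tri[, 2L], , drop = FALSE]
  cc <- mid[tri[, 3L], , drop = FALSE]
  tarea <- 0.5 * sqrt(rowSums(.cross(b - a, cc - a)^2))
  .scatter_thirds(tarea, tri, nrow(mid))
}

#' Vertex-wise cortical thickness
#'
#' Euclidean distance between corresponding white and pial vertices.
#'
#' @param surfaces a `surface_pair`.
#' @return numeric per-vertex thickness (mm).
#' @export
vertex_thickness <- function(surfaces) {
  sqrt(rowSums((surfaces$pial - surfaces$white)^2))
}

#' Vertex-wise cortical volume
#'
#' For each triangle, the oblique truncated prism between its white copy
#' (A, B, C) and pial copy (D, E, F) is decomposed into the three tetrahedra
#' (A,B,C,D), (B,C,D,E), (C,D,E,F), whose signed volumes sum exactly to the
#' prism volume; each prism's volume is split equally among the triangle's
#' three vertices, so vertex volumes sum exactly to the total ribbon volume.
#' Self-intersecting prisms can yield negative signed volumes; these are
#' clamped to 0 and counted in the `clamped` attribute.
#'
#' @param surfaces a `surface_pair` with consistently outward-oriented
#'   triangles.
#' @return numeric per-vertex volume (mm^3) with attribute `clamped`
#'   (number of prisms clamped to zero).
#' @export
vertex_volume <- function(surfaces) {
  tri <- surfaces$triangles
  A <- surfaces$white[tri[, 1L], , drop = FALSE]
  B <- surfaces$white[tri[, 2L], , drop = FALSE]
  C <- surfaces$white[tri[, 3L], , drop = FALSE]
  D1 <- surfaces$pial[tri[, 1L], , drop = FALSE]
  D2 <- surfaces$pial[tri[, 2L], , drop = FALSE]
  D3 <- surfaces$pial[tri[, 3L], , drop = FALSE]
  vol <- .tet_vol(A, B, C, D1) + .tet_vol(B, C, D1, D2) +
    .tet_vol(C, D1, D2, D3)
  clamped <- sum(vol < 0)
  if (clamped > 0) {
    warning(sprintf("%d prisms with negative signed volume clamped to 0",
                    clamped))
    vol <- pmax(vol, 0)
  }
  out <- .scatter_thirds(vol, tri, nrow(surfaces$white))
  attr(out, "clamped") <- clamped
  out
}

.tet_vol <- function(a, b, cc, d) {
  u <- b - a; v <- cc - a; w <- d - a
  (u[, 1L] * (v[, 2L] * w[, 3L] - v[, 3L] * w[, 2L]) -
     u[, 2L] * (v[, 1L] * w[, 3L] - v[, 3L] * w[, 1L]) +
     u[, 3L] * (v[, 1L] * w[, 2L] - v[, 2L] * w[, 1L])) / 6
}

.scatter_thirds <- function(per_triangle, tri, n_vertices) {
  out <- numeric(n_vertices)
  contrib <- rep(per_triangle / 3, 3L)
  idx <- c(tri[, 1L], tri[, 2L], tri[, 3L])
  agg <- rowsum(contrib, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Vertex-wise morphometry table
#'
#' @param surfaces a `surface_pair`.
#' @return object of class `vertex_morphometry`: data frame with columns
#'   `area` (mm^2), `thickness` (mm), `volume` (mm^3), one row per vertex.
#' @export
vertex_morphometry <- function(surfaces) {
  out <- data.frame(area = vertex_area(surfaces),
                    thickness = vertex_thickness(surfaces),
                    volume = as.numeric(vertex_volume(surfaces)))
  class(out) <- c("vertex_morphometry", "data.frame")
  out
}
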