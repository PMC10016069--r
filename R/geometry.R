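#' Triangulated icosphere
#'
#' Builds a geodesic sphere by recursive midpoint subdivision of a regular
#' icosahedron, reprojecting new vertices onto the sphere after each split.
#' The icosahedron is oriented with a vertex at the north pole (+z), so
#' vertex 1 always lies at `(0, 0, radius)`.  The vertex count at level L is
#' `10 * 4^L + 2`; all triangles are consistently outward-oriented.
#'
#' @param level integer >= 0, number of subdivision rounds.
#' @param radius sphere radius (mm).
#' @return list with `vertices` (V x 3 numeric) and `triangles`
#'   (T x 3 integer, 1-based).
#' @export
icosphere <- function(level = 3L, radius = 1) {
  stopifnot(length(level) == 1L, level >= 0L, radius > 0)
  level <- as.integer(level)
  zc <- 1 / sqrt(5)
  rc <- 2 / sqrt(5)
  a_top <- 2 * pi * (0:4) / 5
  a_bot <- a_top + pi / 5
  v <- rbind(
    c(0, 0, 1),
    cbind(rc * cos(a_top), rc * sin(a_top), zc),
    cbind(rc * cos(a_bot), rc * sin(a_bot), -zc),
    c(0, 0, -1)
  )
  k <- 0:4
  kn <- (k + 1L) %% 5L
  tri <- rbind(
    cbind(1L, 2L + k, 2L + kn),                 # top cap
    cbind(2L + k, 7L + k, 2L + kn),             # upper band
    cbind(2L + kn, 7L + k, 7L + kn),            # lower band
    cbind(12L, 7L + kn, 7L + k)                 # bottom cap
  )
  # enforce outward orientation on the base solid
  tri <- .orient_outward(v, tri)
  for (i in seq_len(level)) {
    s <- .subdivide_sphere(v, tri)
    v <- s$vertices
    tri <- s$triangles
  }
  dimnames(v) <- NULL
  dimnames(tri) <- NULL
  list(vertices = v * radius, triangles = tri)
}

.orient_outward <- function(v, tri) {
  a <- v[tri[, 1L], , drop = FALSE]
  b <- v[tri[, 2L], , drop = FALSE]
  cc <- v[tri[, 3L], , drop = FALSE]
  n <- .cross(b - a, cc - a)
  cen <- (a + b + cc) / 3
  flip <- rowSums(n * cen) < 0
  if (any(flip)) tri[flip, c(2L, 3L)] <- tri[flip, c(3L, 2L)]
  tri
}

.cross <- function(u, w) {
  cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
        u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
        u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
}

.subdivide_sphere <- function(v, tri) {
  nv <- nrow(v)
  e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  lo <- pmin(e[, 1L], e[, 2L])
  hi <- pmax(e[, 1L], e[, 2L])
  key <- lo * (nv + 1) + hi
  uk <- !duplicated(key)
  mid_id <- match(key, key[uk]) + nv
  mids <- (v[lo[uk], , drop = FALSE] + v[hi[uk], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  nt <- nrow(tri)
  m12 <- mid_id[seq_len(nt)]
  m23 <- mid_id[nt + seq_len(nt)]
  m31 <- mid_id[2L * nt + seq_len(nt)]
  tri2 <- rbind(
    cbind(tri[, 1L], m12, m31),
    cbind(tri[, 2L], m23, m12),
    cbind(tri[, 3L], m31, m23),
    cbind(m12, m23, m31)
  )
  list(vertices = rbind(v, mids), triangles = tri2)
}

#' White/pial surface pair with shared topology
#'
#' @param white,pial V x 3 vertex coordinate matrices (world mm, RAS).
#' @param triangles T x 3 integer matrix of 1-based vertex indices shared by
#'   both meshes.
#' @return object of class `surface_pair`.
#' @export
surface_pair <- function(white, pial, triangles) {
  white <- as.matrix(white); pial <- as.matrix(pial)
  triangles <- matrix(as.integer(triangles), ncol = 3L)
  if (!identical(dim(white), dim(pial)))
    stop("white and pial must have identical dimensions")
  if (ncol(white) != 3L) stop("vertices must be V x 3")
  if (max(triangles) > nrow(white) || min(triangles) < 1L)
    stop("triangle indices out of range")
  structure(list(white = white, pial = pial, triangles = triangles),
            class = "surface_pair")
}

#' @export
print.surface_pair <- function(x, ...) {
  cat(sprintf("surface_pair: %d vertices, %d triangles\n",
              nrow(x$white), nrow(x$triangles)))
  invisible(x)
}

#' Edge adjacency of a triangle mesh
#'
#' Edge-based vertex connectivity used by smoothing, mode filtering and
#' connected-component extraction.
#'
#' @param triangles T x 3 integer matrix (1-based) or a `surface_pair`.
#' @param n_vertices number of vertices; inferred from the triangle list if
#'   omitted.
#' @return object of class `mesh_adjacency`: list with `edges` (directed
#'   E x 2, both orders present, deduplicated), `degree` (per-vertex integer)
#'   and `matrix` (sparse V x V 0/1 adjacency).
#' @export
mesh_adjacency <- function(triangles, n_vertices = NULL) {
  if (inherits(triangles, "surface_pair")) {
    if (is.null(n_vertices)) n_vertices <- nrow(triangles$white)
    triangles <- triangles$triangles
  }
  if (is.null(n_vertices)) n_vertices <- max(triangles)
  e <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)], triangles[, c(3L, 1L)])
  e <- rbind(e, e[, c(2L, 1L)])
  e <- e[!duplicated(e[, 1L] * (n_vertices + 1) + e[, 2L]), , drop = FALSE]
  deg <- tabulate(e[, 1L], nbins = n_vertices)
  A <- Matrix::sparseMatrix(i = e[, 1L], j = e[, 2L], x = 1,
                            dims = c(n_vertices, n_vertices))
  structure(list(edges = e, degree = deg, matrix = A,
                 n_vertices = n_vertices),
            class = "mesh_adjacency")
}

#' Angular distance of vertices from a reference direction
#'
#' @param vertices V x 3 coordinates (any radius; directions are normalized).
#' @param center unit 3-vector.
#' @return angles in radians, in `[0, pi]`.
#' @export
angular_distance <- function(vertices, center) {
  center <- center / sqrt(sum(center^2))
  u <- vertices / sqrt(rowSums(vertices^2))
  acos(pmin(1, pmax(-1, as.vector(u %*% center))))
}

# orthonormal basis (e1, e2, mu) with third axis along mu
.orthobasis <- function(mu) {
  mu <- mu / sqrt(sum(mu^2))
  ref <- if (abs(mu[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2L] * e1[3L] - mu[3L] * e1[2L],
          mu[3L] * e1[1L] - mu[1L] * e1[3L],
          mu[1L] * e1[2L] - mu[2L] * e1[1L])
  rbind(e1, e2, mu)
}
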