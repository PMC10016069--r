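#' Laplacian smoothing configuration
#'
#' @param iterations non-negative integer (default 2).
#' @param lambda step size in (0, 1) (default 0.3).
#' @return object of class `smoothing_config`.
#' @export
smoothing_config <- function(iterations = 2L, lambda = 0.3) {
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("iterations must be >= 0")
  if (!(lambda > 0 && lambda < 1)) stop("lambda must lie in (0, 1)")
  structure(list(iterations = iterations, lambda = lambda),
            class = "smoothing_config")
}

#' Laplacian smoothing of a vertex scalar map
#'
#' Per iteration each vertex moves toward the mean of its edge neighbors:
#' `v <- v + lambda * (mean(neighbors) - v)`.  Missing (`NA`) vertices are
#' excluded from neighbor averages and stay missing; vertices without any
#' finite neighbor are left unchanged.  The operation is a contraction: the
#' output range is contained in the input range.
#'
#' @param values numeric per-vertex vector (may contain `NA`).
#' @param adjacency a `mesh_adjacency`.
#' @param config a `smoothing_config`.
#' @return smoothed numeric vector.
#' @export
laplacian_smooth <- function(values, adjacency, config = smoothing_config()) {
  v <- as.numeric(values)
  if (length(v) != adjacency$n_vertices)
    stop("values length does not match adjacency")
  A <- adjacency$matrix
  miss <- !is.finite(v)
  for (i in seq_len(config$iterations)) {
    fin <- is.finite(v)
    v0 <- ifelse(fin, v, 0)
    s <- as.vector(A %*% v0)
    n <- as.vector(A %*% as.numeric(fin))
    upd <- fin & n > 0
    v[upd] <- v[upd] + config$lambda * (s[upd] / n[upd] - v[upd])
  }
  v[miss] <- NA_real_
  v
}

#' Threshold a vertex map inside a restriction mask
#'
#' Strict inequality in the stated direction: for ODI-based segmentation
#' vertices strictly below the threshold are included, for FA-based
#' segmentation vertices strictly above.  The result is intersected with
#' the restriction mask; `NA` vertices are never included.
#'
#' @param values numeric per-vertex vector.
#' @param threshold scalar in `[0, 1]`.
#' @param direction `"below"` (ODI) or `"above"` (FA).
#' @param restriction integer vertex indices (1-based) or logical mask
#'   limiting where the parcel may appear; `NULL` means no restriction.
#' @return logical per-vertex mask.
#' @export
threshold_mask <- function(values, threshold, direction = c("below", "above"),
                           restriction = NULL) {
  direction <- match.arg(direction)
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  m <- if (direction == "below") values < threshold else values > threshold
  m[is.na(m)] <- FALSE
  if (!is.null(restriction)) {
    r <- .restriction_logical(restriction, length(values))
    m <- m & r
  }
  m
}

.restriction_logical <- function(restriction, n) {
  if (is.logical(restriction)) {
    if (length(restriction) != n) stop("restriction mask length mismatch")
    restriction
  } else {
    r <- rep(FALSE, n)
    idx <- as.integer(restriction)
    if (length(idx) == 0L) stop("restriction mask is empty")
    if (any(idx < 1L | idx > n)) stop("restriction indices out of range")
    r[idx] <- TRUE
    r
  }
}

#' Mode-filter regularization of a vertex label mask
#'
#' Each vertex synchronously takes the majority label of its closed
#' neighborhood (itself plus edge neighbors); exact ties keep the current
#' label.
#'
#' @param mask logical per-vertex vector.
#' @param adjacency a `mesh_adjacency`.
#' @param iterations number of synchronous passes (default 1).
#' @return regularized logical mask.
#' @export
mode_filter <- function(mask, adjacency, iterations = 1L) {
  m <- as.logical(mask)
  if (length(m) != adjacency$n_vertices)
    stop("mask length does not match adjacency")
  A <- adjacency$matrix
  total <- adjacency$degree + 1
  for (i in seq_len(iterations)) {
    cnt <- as.vector(A %*% as.numeric(m)) + m
    m <- ifelse(2 * cnt > total, TRUE, ifelse(2 * cnt < total, FALSE, m))
  }
  m
}

#' Largest edge-connected component of a vertex mask
#'
#' Keeps only the connected true component with the most vertices.  Size
#' ties are broken by the largest summed vertex area, then by the lowest
#' minimum vertex index; an empty mask passes through unchanged.
#'
#' @param mask logical per-vertex vector.
#' @param adjacency a `mesh_adjacency`.
#' @param area optional per-vertex area used for the tie-break.
#' @return logical mask containing a single component (or empty).
#' @export
largest_component <- function(mask, adjacency, area = NULL) {
  m <- as.logical(mask)
  idx <- which(m)
  if (length(idx) == 0L) return(m)
  e <- adjacency$edges
  keep <- m[e[, 1L]] & m[e[, 2L]] & e[, 1L] < e[, 2L]
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(e[keep, 1L], idx), to = match(e[keep, 2L], idx)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(idx)))
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L && !is.null(area)) {
    carea <- vapply(cand, function(ci) sum(area[idx[comp == ci]]), numeric(1L))
    cand <- cand[carea == max(carea)]
  }
  if (length(cand) > 1L) {
    cmin <- vapply(cand, function(ci) min(idx[comp == ci]), numeric(1L))
    cand <- cand[which.min(cmin)]
  }
  out <- rep(FALSE, length(m))
  out[idx[comp == cand[1L]]] <- TRUE
  out
}

#' Parcel metrics from a vertex mask and morphometry
#'
#' Surface area and volume are sums of the per-vertex measures over the
#' mask; mean thickness is the area-weighted vertex thickness; percent
#' metrics divide by whole-cortex totals.  An empty mask reports zeros with
#' `empty = TRUE`.
#'
#' @param mask logical per-vertex vector.
#' @param morphometry a `vertex_morphometry` on the same topology.
#' @param totals list with `area` and `volume` whole-cortex totals
#'   (defaults: sums over all vertices).
#' @return list with `area`, `mean_thickness`, `volume`, `percent_area`,
#'   `percent_volume`, `n_vertices`, `empty`.
#' @export
parcel_metrics <- function(mask, morphometry, totals = NULL) {
  if (length(mask) != nrow(morphometry))
    stop("mask and morphometry topology mismatch")
  if (is.null(totals))
    totals <- list(area = sum(morphometry$area),
                   volume = sum(morphometry$volume))
  if (!any(mask)) {
    return(list(area = 0, mean_thickness = 0, volume = 0,
                percent_area = 0, percent_volume = 0,
                n_vertices = 0L, empty = TRUE))
  }
  a <- morphometry$area[mask]
  list(area = sum(a),
       mean_thickness = sum(a * morphometry$thickness[mask]) / sum(a),
       volume = sum(morphometry$volume[mask]),
       percent_area = 100 * sum(a) / totals$area,
       percent_volume = 100 * sum(morphometry$volume[mask]) / totals$volume,
       n_vertices = sum(mask), empty = FALSE)
}

#' Segment the frontoinsular parcel from a vertex microstructure map
#'
#' Full chain: Laplacian smoothing of the vertex map, strict thresholding
#' inside the restriction mask, mode-filter regularization, largest
#' connected component, and parcel metrics.  Deterministic: identical
#' inputs always give identical masks.
#'
#' @param values numeric per-vertex vector or `vertex_map` (microstructure
#'   parameter on the parcellation topology).
#' @param adjacency a `mesh_adjacency`.
#' @param morphometry a `vertex_morphometry`.
#' @param restriction vertex indices or logical restriction mask.
#' @param threshold scalar in `[0, 1]`.
#' @param direction `"below"` for ODI, `"above"` for FA.
#' @param smoothing a `smoothing_config` (default 2 iterations,
#'   lambda 0.3).
#' @param mode_iterations mode-filter passes (default 1).
#' @param totals optional whole-cortex totals for percent metrics.
#' @return object of class `parcel_result`: the `parcel_metrics` list plus
#'   `mask`, `threshold`, `direction`.
#' @export
parcellate <- function(values, adjacency, morphometry, restriction,
                       threshold, direction = c("below", "above"),
                       smoothing = smoothing_config(), mode_iterations = 1L,
                       totals = NULL) {
  direction <- match.arg(direction)
  if (inherits(values, "vertex_map")) values <- values$mean
  sm <- laplacian_smooth(values, adjacency, smoothing)
  m <- threshold_mask(sm, threshold, direction, restriction)
  m <- mode_filter(m, adjacency, mode_iterations)
  m <- largest_component(m, adjacency, area = morphometry$area)
  res <- parcel_metrics(m, morphometry, totals)
  res$mask <- m
  res$threshold <- threshold
  res$direction <- direction
  class(res) <- "parcel_result"
  res
}

#' @export
print.parcel_result <- function(x, ...) {
  cat(sprintf(paste0("parcel_result: %d vertices, area %.2f mm^2, ",
                     "thickness %.3f mm, volume %.2f mm^3 ",
                     "(%.2f%% area, %.2f%% volume)\n"),
              x$n_vertices, x$area, x$mean_thickness, x$volume,
              x$percent_area, x$percent_volume))
  invisible(x)
}

#' Dice overlap between two vertex masks
#'
#' @param a,b logical masks on the same topology.
#' @return Dice coefficient in `[0, 1]` (1 when both masks are empty).
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("mask length mismatch")
  if (!any(a) && !any(b)) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}
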