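#' Depth-sampling configuration
#'
#' Controls the two-stage cortical sampling scheme: `n_points` sampling
#' positions equally spaced from the white to the pial vertex (inclusive),
#' Gaussian depth weighting centered at the cortical midpoint with unit
#' weight and `boundary_weight` at both tissue boundaries, and z-score
#' outlier rejection.
#'
#' @param n_points odd integer >= 3 (default 15), so one sample sits exactly
#'   at the midpoint.
#' @param midpoint_weight weight at normalized depth 0.5 (default 1).
#' @param boundary_weight weight at the inner and outer boundaries
#'   (default 0.05).
#' @param z_threshold outlier rejection threshold (default 3).
#' @param interpolation `"tricubic"` (default) or `"trilinear"`.
#' @return object of class `sampling_config`.
#' @export
sampling_config <- function(n_points = 15L, midpoint_weight = 1,
                            boundary_weight = 0.05, z_threshold = 3,
                            interpolation = c("tricubic", "trilinear")) {
  n_points <- as.integer(n_points)
  if (n_points < 3L || n_points %% 2L == 0L)
    stop("n_points must be odd and >= 3")
  if (!(boundary_weight > 0 && boundary_weight < midpoint_weight))
    stop("need 0 < boundary_weight < midpoint_weight")
  structure(list(n_points = n_points, midpoint_weight = midpoint_weight,
                 boundary_weight = boundary_weight, z_threshold = z_threshold,
                 interpolation = match.arg(interpolation)),
            class = "sampling_config")
}

#' Gaussian depth weights for the cortical sampling points
#'
#' Weights follow a Gaussian in normalized depth t in `[0, 1]` centered at
#' the midpoint (weight `midpoint_weight`, by default exactly 1) with the
#' standard deviation solved so the two boundary samples receive exactly
#' `boundary_weight` (by default 0.05), de-emphasizing voxels prone to
#' partial-volume contamination at the tissue boundaries.
#'
#' @param config a `sampling_config`.
#' @return numeric vector of length `n_points`.
#' @export
depth_weights <- function(config = sampling_config()) {
  t <- seq(0, 1, length.out = config$n_points)
  sigma2 <- 0.25 / (2 * log(config$midpoint_weight / config$boundary_weight))
  config$midpoint_weight * exp(-(t - 0.5)^2 / (2 * sigma2))
}

#' Robust weighted mean with single-pass z-score outlier rejection
#'
#' Computes the unweighted mean and SD of the finite samples, excludes
#' samples with `|z| > z_threshold`, then recomputes a weighted mean and SD
#' over the survivors.  Outlier detection is unweighted; the weights enter
#' only the recomputed estimate.
#'
#' @param values,weights equal-length numeric vectors.
#' @param z_threshold rejection threshold (default 3).
#' @return list with `mean`, `sd` (weighted, population form), `n_retained`
#'   and `missing` (TRUE when no finite value is available).
#' @export
robust_weighted_mean <- function(values, weights, z_threshold = 3) {
  if (length(values) != length(weights))
    stop("values and weights must have equal length")
  fin <- is.finite(values)
  if (!any(fin)) {
    return(list(mean = NA_real_, sd = NA_real_, n_retained = 0L,
                missing = TRUE))
  }
  v <- values[fin]; w <- weights[fin]
  m <- mean(v); s <- sd(v)
  # numerically-constant samples: no outliers (guards fp jitter ~ 1e-16)
  degenerate <- is.na(s) || s <= max(abs(m), 1) * 1e-12
  keep <- if (degenerate) rep(TRUE, length(v)) else
    abs(v - m) <= z_threshold * s
  v <- v[keep]; w <- w[keep]
  wm <- sum(w * v) / sum(w)
  ws <- sqrt(sum(w * (v - wm)^2) / sum(w))
  list(mean = wm, sd = ws, n_retained = length(v), missing = FALSE)
}

#' Project a parameter volume onto a cortical surface pair
#'
#' For each vertex, `n_points` positions are placed at equal spacing along
#' the straight segment from the white to the pial vertex (both endpoints
#' included), the volume is interpolated at each position, values are
#' weighted by the Gaussian depth profile, and a robust weighted mean is
#' formed after z-score outlier rejection.  Vertices whose samples all fall
#' outside the field of view are flagged missing (`NA`), never zero.
#'
#' @param volume a `scalar_volume` in the same world space as the surfaces.
#' @param surfaces a `surface_pair` (world mm coordinates).
#' @param config a `sampling_config`.
#' @return object of class `vertex_map`: list with `mean`, `sd`,
#'   `n_retained`, `missing` (per-vertex vectors) and `n_vertices`.
#' @export
sample_cortex <- function(volume, surfaces, config = sampling_config()) {
  V <- nrow(surfaces$white)
  np <- config$n_points
  t <- seq(0, 1, length.out = np)
  # (V*np) x 3 positions, vertex-major
  P <- matrix(0, V * np, 3L)
  for (k in seq_len(np)) {
    idx <- seq.int(k, by = np, length.out = V)
    P[idx, ] <- (1 - t[k]) * surfaces$white + t[k] * surfaces$pial
  }
  vals <- interpolate_volume(volume, P, method = config$interpolation)
  M <- matrix(vals, nrow = V, ncol = np, byrow = TRUE)
  w <- depth_weights(config)
  st <- .robust_rows(M, w, config$z_threshold)
  structure(list(mean = st$mean, sd = st$sd, n_retained = st$n,
                 missing = st$missing, n_vertices = V),
            class = "vertex_map")
}

#' @export
print.vertex_map <- function(x, ...) {
  cat(sprintf("vertex_map: %d vertices (%d missing), mean range [%.4g, %.4g]\n",
              x$n_vertices, sum(x$missing),
              suppressWarnings(min(x$mean, na.rm = TRUE)),
              suppressWarnings(max(x$mean, na.rm = TRUE))))
  invisible(x)
}

# row-wise vectorized version of robust_weighted_mean
.robust_rows <- function(M, w, z_threshold) {
  fin <- is.finite(M)
  cnt <- rowSums(fin)
  M0 <- ifelse(fin, M, 0)
  m <- rowSums(M0) / pmax(cnt, 1L)
  ss <- rowSums(ifelse(fin, (M - m)^2, 0))
  s <- sqrt(ss / pmax(cnt - 1L, 1L))
  s[cnt < 2L] <- 0
  degenerate <- s <= pmax(abs(m), 1) * 1e-12
  keep <- fin & (degenerate | abs(M - m) <= z_threshold * s)
  W <- matrix(w, nrow(M), length(w), byrow = TRUE) * keep
  sw <- rowSums(W)
  wm <- rowSums(W * M0) / sw
  ws <- sqrt(rowSums(W * ifelse(keep, (M - wm)^2, 0)) / sw)
  missing <- cnt == 0L
  wm[missing] <- NA_real_; ws[missing] <- NA_real_
  list(mean = wm, sd = ws, n = as.integer(rowSums(keep)), missing = missing)
}

#' Resample a vertex map onto an atlas topology
#'
#' Barycentric interpolation of per-vertex values through a precomputed
#' spherical-registration correspondence: each atlas vertex is a weighted
#' combination of three subject vertices.  Missing subject vertices are
#' dropped from the combination (weights renormalized); an atlas vertex is
#' missing only when all three corners are missing.
#'
#' @param values numeric per-vertex vector on the subject topology, or a
#'   `vertex_map` (its `mean` is resampled).
#' @param correspondence data frame with integer columns `i1, i2, i3`
#'   (1-based subject vertex indices) and weights `w1, w2, w3`.
#' @return numeric vector, one value per atlas vertex.
#' @export
resample_to_atlas <- function(values, correspondence) {
  if (inherits(values, "vertex_map")) values <- values$mean
  co <- correspondence
  need <- c("i1", "i2", "i3", "w1", "w2", "w3")
  if (!all(need %in% names(co))) stop("correspondence must have columns ",
                                      paste(need, collapse = ", "))
  W <- as.matrix(co[, c("w1", "w2", "w3")])
  if (any(W < -1e-9)) stop("degenerate barycentric weights (negative)")
  if (any(abs(rowSums(W)) < 1e-12)) stop("degenerate barycentric weights (zero sum)")
  Vm <- cbind(values[co$i1], values[co$i2], values[co$i3])
  fin <- is.finite(Vm)
  W2 <- W * fin
  sw <- rowSums(W2)
  out <- rowSums(W2 * ifelse(fin, Vm, 0)) / sw
  out[sw <= 0] <- NA_real_
  out
}

#' Identity correspondence table for a shared topology
#'
#' @param n_vertices number of vertices.
#' @return a correspondence data frame mapping each vertex to itself.
#' @export
identity_correspondence <- function(n_vertices) {
  i <- seq_len(n_vertices)
  data.frame(i1 = i, i2 = i, i3 = i, w1 = 1, w2 = 0, w3 = 0)
}
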