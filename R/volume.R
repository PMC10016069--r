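#' Scalar volume with voxel-to-world affine
#'
#' Minimal 3D image container: a numeric array plus a 4x4 affine mapping
#' 0-based voxel indices to world RAS coordinates in mm (NIfTI convention).
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @return object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("affine is singular")
  structure(list(data = data, affine = affine), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("scalar_volume: %s, voxel sizes %s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(sqrt(colSums(x$affine[1:3, 1:3]^2)), 4),
                    collapse = " x ")))
  invisible(x)
}

#' Read / write scalar volumes as NIfTI
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @rdname volume_io
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  scalar_volume(array(as.numeric(img), dim = dim(img)[1:3]), aff)
}

#' @param volume a `scalar_volume`.
#' @rdname volume_io
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::`sform<-`(img, structure(volume$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert world coordinates to continuous voxel coordinates
#'
#' @param volume a `scalar_volume`.
#' @param points N x 3 world coordinates (mm).
#' @return N x 3 continuous 0-based voxel coordinates.
#' @export
world_to_voxel <- function(volume, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  inv <- solve(volume$affine)
  h <- cbind(points, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

#' Interpolate a volume at world coordinates
#'
#' Tricubic interpolation uses the separable Catmull-Rom kernel (exactly
#' reproduces linear fields); trilinear is available as a faster fallback.
#' Points whose continuous voxel coordinate falls outside the grid are
#' returned as `NA` (the out-of-field sentinel, excluded downstream); kernel
#' support beyond the border is clamped to the edge voxel.
#'
#' @param volume a `scalar_volume`.
#' @param points N x 3 world coordinates (mm).
#' @param method `"tricubic"` (default) or `"trilinear"`.
#' @return numeric vector of length N, `NA` where out of field.
#' @export
interpolate_volume <- function(volume, points,
                               method = c("tricubic", "trilinear")) {
  method <- match.arg(method)
  vx <- world_to_voxel(volume, points)
  .interp_voxel(volume$data, vx, method)
}

.interp_voxel <- function(arr, vx, method) {
  d <- dim(arr)
  x <- vx[, 1L]; y <- vx[, 2L]; z <- vx[, 3L]
  oob <- x < -0.5 | x > d[1L] - 0.5 | y < -0.5 | y > d[2L] - 0.5 |
    z < -0.5 | z > d[3L] - 0.5 | !is.finite(x) | !is.finite(y) | !is.finite(z)
  x[oob] <- 0; y[oob] <- 0; z[oob] <- 0
  if (method == "trilinear") {
    out <- .interp_core(arr, x, y, z, offs = 0:1, wfun = .lin_w)
  } else {
    out <- .interp_core(arr, x, y, z, offs = -1:2, wfun = .catmull_w)
  }
  out[oob] <- NA_real_
  unname(out)
}

# weights for fractional position t, one column per kernel tap
.lin_w <- function(t) cbind(1 - t, t)

.catmull_w <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind((-t3 + 2 * t2 - t) / 2,
        (3 * t3 - 5 * t2 + 2) / 2,
        (-3 * t3 + 4 * t2 + t) / 2,
        (t3 - t2) / 2)
}

# NA-aware separable interpolation (normalized convolution): non-finite
# taps are dropped and the remaining weights renormalized; a point whose
# support retains less than half its weight mass is returned as NA.
.interp_core <- function(arr, x, y, z, offs, wfun) {
  d <- dim(arr)
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  wx <- wfun(x - i0); wy <- wfun(y - j0); wz <- wfun(z - k0)
  out <- numeric(length(x))
  wsum <- numeric(length(x))
  for (a in seq_along(offs)) {
    ia <- pmin(pmax(i0 + offs[a], 0), d[1L] - 1)
    for (b in seq_along(offs)) {
      jb <- pmin(pmax(j0 + offs[b], 0), d[2L] - 1)
      wab <- wx[, a] * wy[, b]
      for (cc in seq_along(offs)) {
        kc <- pmin(pmax(k0 + offs[cc], 0), d[3L] - 1)
        v <- arr[1 + ia + d[1L] * (jb + d[2L] * kc)]
        fin <- is.finite(v)
        w <- wab * wz[, cc] * fin
        out <- out + w * ifelse(fin, v, 0)
        wsum <- wsum + w
      }
    }
  }
  bad <- wsum < 0.5
  out <- out / wsum
  out[bad] <- NA_real_
  out
}

#' Resample a volume onto a target grid through a rigid transform
#'
#' Spatially normalizes a parameter volume into another (typically
#' higher-resolution structural) space with tricubic interpolation.  The
#' transform maps target-space world coordinates to source-space world
#' coordinates; voxels that land outside the source field of view receive
#' `NA`, the sentinel excluded by all downstream sampling.
#'
#' @param volume source `scalar_volume`.
#' @param transform 4x4 rigid world-to-world matrix (target -> source).
#' @param target_affine 4x4 voxel-to-world affine of the output grid.
#' @param target_dim integer length-3 output grid size.
#' @param method interpolation kernel, `"tricubic"` (default) or
#'   `"trilinear"`.
#' @return a `scalar_volume` on the target grid.
#' @export
resample_volume <- function(volume, transform = diag(4), target_affine,
                            target_dim, method = c("tricubic", "trilinear")) {
  method <- match.arg(method)
  transform <- as.matrix(transform)
  R <- transform[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("transform must be rigid (orthonormal rotation block)")
  target_dim <- as.integer(target_dim)
  g <- as.matrix(expand.grid(i = seq_len(target_dim[1L]) - 1,
                             j = seq_len(target_dim[2L]) - 1,
                             k = seq_len(target_dim[3L]) - 1))
  world <- cbind(g, 1) %*% t(target_affine)
  src_world <- world %*% t(transform)
  vals <- .interp_voxel(volume$data,
                        world_to_voxel(volume, src_world[, 1:3]) , method)
  scalar_volume(array(vals, dim = target_dim), target_affine)
}
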