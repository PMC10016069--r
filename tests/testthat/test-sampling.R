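test_that("depth weights hit the calibration points exactly", {
  w <- depth_weights(sampling_config())
  expect_identical(length(w), 15L)
  expect_equal(w[8], 1.0)
  expect_equal(w[1], 0.05)
  expect_equal(w[15], 0.05)
  expect_equal(w, rev(w))  # symmetric about the midpoint
  # different calibration
  w2 <- depth_weights(sampling_config(n_points = 9, boundary_weight = 0.2))
  expect_equal(w2[c(1, 5, 9)], c(0.2, 1, 0.2))
  expect_error(sampling_config(n_points = 10), "odd")
  expect_error(sampling_config(boundary_weight = 2), "boundary_weight")
})

test_that("robust weighted mean rejects spikes and matches the plain mean", {
  # constant values
  r <- robust_weighted_mean(rep(0.4, 15), depth_weights())
  expect_equal(r$mean, 0.4)
  expect_equal(r$n_retained, 15L)
  # planted spike is excluded entirely
  v <- c(rep(0.40, 14), 5.0)
  r2 <- robust_weighted_mean(v, depth_weights())
  expect_equal(r2$mean, 0.40)
  expect_equal(r2$n_retained, 14L)
  # no outliers: equals sum(w v) / sum(w)
  set.seed(4)
  v3 <- runif(15, 0.3, 0.5); w <- depth_weights()
  r3 <- robust_weighted_mean(v3, w)
  expect_equal(r3$mean, sum(w * v3) / sum(w), tolerance = 1e-12)
  # infinite threshold reduces to the plain weighted mean exactly
  v4 <- c(rnorm(14), 50)
  r4 <- robust_weighted_mean(v4, w, z_threshold = Inf)
  expect_identical(r4$mean, sum(w * v4) / sum(w))
  # scaling all weights leaves the mean unchanged
  r5 <- robust_weighted_mean(v3, 7 * w)
  expect_equal(r5$mean, r3$mean, tolerance = 1e-12)
  # all missing
  r6 <- robust_weighted_mean(rep(NA_real_, 15), w)
  expect_true(r6$missing)
  expect_identical(r6$n_retained, 0L)
})

test_that("vectorized row-wise robust mean agrees with the scalar version", {
  set.seed(9)
  w <- depth_weights()
  M <- matrix(rnorm(40 * 15, 0.4, 0.05), 40, 15)
  M[3, 7] <- 9            # spike
  M[5, c(2, 11)] <- NA    # missing samples
  M[9, ] <- NA            # fully missing vertex
  st <- ficmap:::.robust_rows(M, w, 3)
  for (i in seq_len(nrow(M))) {
    r <- robust_weighted_mean(M[i, ], w, 3)
    expect_equal(st$mean[i], r$mean, tolerance = 1e-12)
    expect_equal(st$n[i], r$n_retained)
    expect_equal(st$missing[i], r$missing)
  }
})

test_that("tricubic interpolation reproduces linear fields", {
  n <- 12
  ax <- 0:(n - 1)
  f <- function(x, y, z) 0.2 + 0.03 * x - 0.05 * y + 0.02 * z
  arr <- array(0, c(n, n, n))
  for (k in ax) arr[, , k + 1] <- outer(ax, ax, function(x, y) f(x, y, k))
  vol <- scalar_volume(arr, diag(4))
  set.seed(2)
  pts <- cbind(runif(200, 2, n - 3), runif(200, 2, n - 3), runif(200, 2, n - 3))
  got <- interpolate_volume(vol, pts)
  expect_equal(got, f(pts[, 1], pts[, 2], pts[, 3]), tolerance = 1e-10)
  # out-of-field points are NA, not zero
  expect_true(is.na(interpolate_volume(vol, cbind(-5, 0, 0))))
})

test_that("volume resampling honors identity, constants, and linear ramps", {
  set.seed(3)
  arr <- array(rnorm(10^3), c(10, 10, 10))
  vol <- scalar_volume(arr, diag(4))
  out <- resample_volume(vol, diag(4), diag(4), c(10, 10, 10))
  expect_equal(out$data, arr, tolerance = 1e-10)
  # constant volume through an arbitrary rigid transform stays constant
  cvol <- scalar_volume(array(3.7, c(10, 10, 10)), diag(4))
  tr <- diag(4); tr[1:3, 1:3] <- random_rotation(); tr[1:3, 4] <- c(1, -2, 0.5)
  outc <- resample_volume(cvol, tr, diag(4), c(6, 6, 6))
  inside <- !is.na(outc$data)
  expect_true(any(inside))
  expect_equal(range(outc$data[inside]), c(3.7, 3.7), tolerance = 1e-10)
  # linear ramp through a half-voxel translation (cubic reproduces linears)
  ramp <- array(rep(0:9, each = 1), c(10, 10, 10))
  for (i in 1:10) ramp[i, , ] <- i - 1
  rvol <- scalar_volume(ramp, diag(4))
  tr2 <- diag(4); tr2[1, 4] <- 0.5
  outr <- resample_volume(rvol, tr2, diag(4), c(6, 10, 10))
  expect_equal(outr$data[3, 5, 5], 2 + 0.5, tolerance = 1e-6)
  expect_error(resample_volume(rvol, diag(c(2, 1, 1, 1)), diag(4), c(5, 5, 5)),
               "rigid")
})

test_that("cortical sampling reproduces constant and spiked fields", {
  spec <- phantom_spec(subdivision_level = 2)
  surf <- make_phantom_surfaces(spec)
  vols <- make_microstructure_phantom(spec)
  cvol <- scalar_volume(array(0.42, dim(vols$odi$data)), vols$odi$affine)
  vm <- sample_cortex(cvol, surf)
  expect_equal(vm$mean, rep(0.42, nrow(surf$white)), tolerance = 1e-9)
  expect_true(all(vm$n_retained == 15L))
  # noiseless phantom: vertices inside the patch recover the patch value
  vm2 <- sample_cortex(vols$odi, surf)
  pv <- patch_vertices(surf, spec)
  interior <- pv[angular_distance(surf$white[pv, ], spec$patch_center) <
                   spec$patch_angular_radius - 0.15]
  expect_equal(vm2$mean[interior], rep(spec$odi_patch, length(interior)),
               tolerance = 1e-3)
})

test_that("atlas resampling is exact for identity, constant and linear maps", {
  spec <- phantom_spec(subdivision_level = 2)
  surf <- make_phantom_surfaces(spec)
  V <- nrow(surf$white)
  vals <- rnorm(V)
  expect_identical(resample_to_atlas(vals, identity_correspondence(V)), vals)
  # barycentric interpolation of a linear-in-position map is exact
  tri <- surf$triangles[1:50, ]
  set.seed(8)
  w <- matrix(runif(150), 50, 3); w <- w / rowSums(w)
  co <- data.frame(i1 = tri[, 1], i2 = tri[, 2], i3 = tri[, 3],
                   w1 = w[, 1], w2 = w[, 2], w3 = w[, 3])
  lin <- surf$white %*% c(0.1, -0.2, 0.3)
  got <- resample_to_atlas(as.vector(lin), co)
  pos <- w[, 1] * surf$white[tri[, 1], ] + w[, 2] * surf$white[tri[, 2], ] +
    w[, 3] * surf$white[tri[, 3], ]
  expect_equal(got, as.vector(pos %*% c(0.1, -0.2, 0.3)), tolerance = 1e-6)
  # missing propagation: all corners missing -> missing; partial -> renormalized
  vals2 <- vals; vals2[co$i1[1]] <- NA
  got2 <- resample_to_atlas(vals2, co)
  expect_false(is.na(got2[1]))
  vals3 <- vals; vals3[c(co$i1[1], co$i2[1], co$i3[1])] <- NA
  expect_true(is.na(resample_to_atlas(vals3, co)[1]))
  bad <- co; bad$w1[1] <- 0; bad$w2[1] <- 0; bad$w3[1] <- 0
  expect_error(resample_to_atlas(vals, bad), "degenerate")
})
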