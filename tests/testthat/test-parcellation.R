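test_that("Laplacian smoothing has the exact impulse response", {
  s <- icosphere(2)
  adj <- mesh_adjacency(s$triangles)
  V <- nrow(s$vertices)
  # constant map is a fixed point
  expect_equal(laplacian_smooth(rep(2.5, V), adj,
                                smoothing_config(iterations = 5)), rep(2.5, V))
  # zero iterations is the identity
  set.seed(1); v <- rnorm(V)
  expect_identical(laplacian_smooth(v, adj, smoothing_config(iterations = 0)), v)
  # unit impulse, one iteration: center 1 - lambda, neighbors lambda/deg
  imp <- rep(0, V); imp[1] <- 1
  out <- laplacian_smooth(imp, adj, smoothing_config(iterations = 1, lambda = 0.3))
  expect_equal(out[1], 0.7)
  nb <- adj$edges[adj$edges[, 1] == 1, 2]
  expect_equal(out[nb], rep(0.3 / adj$degree[nb[1]], length(nb)))
  # contraction: output range within input range
  sm <- laplacian_smooth(v, adj)
  expect_gte(min(sm), min(v))
  expect_lte(max(sm), max(v))
  # missing vertices stay missing and do not poison neighbors
  v2 <- v; v2[10] <- NA
  sm2 <- laplacian_smooth(v2, adj)
  expect_true(is.na(sm2[10]))
  expect_true(all(is.finite(sm2[-10])))
})

test_that("threshold direction, strictness and restriction behave as stated", {
  vals <- c(0.1, 0.3, 0.375, 0.5, NA)
  expect_equal(threshold_mask(vals, 0.375, "below"),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))  # strict; NA excluded
  expect_equal(threshold_mask(vals, 0.375, "above"),
               c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(threshold_mask(vals, 0, "below"), rep(FALSE, 5))
  expect_equal(threshold_mask(vals, 1, "below", restriction = c(1L, 2L)),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(threshold_mask(vals, 1.5, "below"), "threshold")
})

test_that("mode filter takes closed-neighborhood majorities with ties kept", {
  s <- icosphere(1)
  adj <- mesh_adjacency(s$triangles)
  V <- nrow(s$vertices)
  expect_equal(mode_filter(rep(TRUE, V), adj), rep(TRUE, V))
  # isolated true vertex flips to false
  m <- rep(FALSE, V); m[1] <- TRUE
  expect_equal(mode_filter(m, adj), rep(FALSE, V))
  # engineered tie: vertex 1 has degree 6 at level 1? choose a degree-5
  # vertex: closed neighborhood size 6; 3 true (incl self) vs 3 false = tie
  v5 <- which(adj$degree == 5)[1]
  nb <- adj$edges[adj$edges[, 1] == v5, 2]
  m2 <- rep(FALSE, V); m2[c(v5, nb[1:2])] <- TRUE
  # isolate the tie: make the two true neighbors keep majorities irrelevant;
  # we only check the center's tie rule
  expect_true(mode_filter(m2, adj)[v5])
  m3 <- rep(TRUE, V); m3[c(v5, nb[1:2])] <- FALSE
  expect_false(mode_filter(m3, adj)[v5])
})

test_that("largest component matches a brute-force BFS oracle", {
  s <- icosphere(2)
  adj <- mesh_adjacency(s$triangles)
  V <- nrow(s$vertices)
  set.seed(21)
  for (rep_i in 1:10) {
    m <- runif(V) < 0.3
    got <- largest_component(m, adj)
    lab <- bfs_components(m, s$triangles)
    if (!any(m)) {
      expect_equal(got, m)
    } else {
      sizes <- table(lab[lab > 0])
      best <- as.integer(names(sizes)[sizes == max(sizes)])
      # oracle: union over tied components must contain the result;
      # result must be one full component of maximal size
      expect_true(sum(got) == max(sizes))
      expect_true(any(vapply(best, function(bl)
        identical(which(lab == bl), which(got)), logical(1))))
    }
  }
  expect_equal(largest_component(rep(FALSE, V), adj), rep(FALSE, V))
})

test_that("parcel metrics report sums, weighted thickness and percentages", {
  sp <- make_phantom_surfaces(phantom_spec(subdivision_level = 2))
  morph <- vertex_morphometry(sp)
  V <- nrow(sp$white)
  all_mask <- rep(TRUE, V)
  pm <- parcel_metrics(all_mask, morph)
  expect_equal(pm$percent_area, 100)
  expect_equal(pm$percent_volume, 100)
  expect_equal(pm$mean_thickness, 3, tolerance = 1e-9)
  empty <- parcel_metrics(rep(FALSE, V), morph)
  expect_true(empty$empty)
  expect_equal(empty$volume, 0)
  expect_equal(empty$mean_thickness, 0)
  # planted patch volume close to the analytic spherical-cap shell volume
  spec <- phantom_spec(subdivision_level = 4)
  sp4 <- make_phantom_surfaces(spec)
  m4 <- vertex_morphometry(sp4)
  gt <- rep(FALSE, nrow(sp4$white))
  gt[patch_vertices(sp4, spec)] <- TRUE
  got <- parcel_metrics(gt, m4)$volume
  cap <- function(r) 2 / 3 * pi * r^3 * (1 - cos(spec$patch_angular_radius))
  analytic <- cap(spec$pial_radius) - cap(spec$white_radius)
  expect_lt(abs(got - analytic) / analytic, 0.02)
})

test_that("the parcellation chain is deterministic and threshold-monotone", {
  spec <- phantom_spec(subdivision_level = 3)
  surf <- make_phantom_surfaces(spec)
  adj <- mesh_adjacency(surf)
  morph <- vertex_morphometry(surf)
  vm <- sample_cortex(make_microstructure_phantom(spec)$odi, surf)
  restr <- rep(TRUE, nrow(surf$white))
  r1 <- parcellate(vm, adj, morph, restr, 0.375, "below")
  r2 <- parcellate(vm, adj, morph, restr, 0.375, "below")
  expect_identical(r1$mask, r2$mask)
  # raising an ODI threshold never shrinks the pre-regularization mask
  sm <- laplacian_smooth(vm$mean, adj)
  m_lo <- threshold_mask(sm, 0.3, "below")
  m_hi <- threshold_mask(sm, 0.45, "below")
  expect_true(all(m_hi[m_lo]))
})

test_that("the planted patch is recovered exactly without noise", {
  spec <- phantom_spec()
  surf <- make_phantom_surfaces(spec)
  adj <- mesh_adjacency(surf)
  morph <- vertex_morphometry(surf)
  vm <- sample_cortex(make_microstructure_phantom(spec)$odi, surf)
  res <- parcellate(vm, adj, morph, rep(TRUE, nrow(surf$white)),
                    0.375, "below")
  gt <- rep(FALSE, nrow(surf$white))
  gt[patch_vertices(surf, spec)] <- TRUE
  expect_equal(dice(res$mask, gt), 1.0)
})
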