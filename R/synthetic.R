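#' Phantom specification
#'
#' Parameters of the concentric-icosphere cortical phantom: a white/pial
#' surface pair, and ODI/FA parameter volumes with a planted low-dispersion
#' patch emulating the frontoinsular microstructure signature (the patch has
#' lower ODI and higher FA than the background cortex).
#'
#' @param subdivision_level icosphere subdivision level (>= 1).
#' @param white_radius,pial_radius sphere radii in mm
#'   (`pial_radius > white_radius > 0`).
#' @param patch_center unit direction of the patch center.
#' @param patch_angular_radius patch radius in radians.
#' @param odi_background,odi_patch ODI values in (0, 1); the patch must be
#'   the low-dispersion side (`odi_patch < odi_background`).
#' @param fa_background,fa_patch FA values in (0, 1).
#' @param voxel_size parameter-volume voxel size in mm; must not exceed the
#'   ribbon thickness.
#' @param noise_sd additive Gaussian noise SD on the parameter volumes.
#' @param seed RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(subdivision_level = 3L, white_radius = 30,
                         pial_radius = 33, patch_center = c(0, 0, 1),
                         patch_angular_radius = 0.52,
                         odi_background = 0.5, odi_patch = 0.25,
                         fa_background = 0.2, fa_patch = 0.5,
                         voxel_size = 1, noise_sd = 0, seed = 1L) {
  if (!(pial_radius > white_radius && white_radius > 0))
    stop("need pial_radius > white_radius > 0")
  if (!(odi_patch < odi_background))
    stop("patch must be low-dispersion: odi_patch < odi_background")
  for (v in c(odi_background, odi_patch, fa_background, fa_patch))
    if (v <= 0 || v >= 1) stop("parameter values must lie in (0, 1)")
  if (voxel_size > pial_radius - white_radius)
    stop("voxel_size exceeds ribbon thickness: ribbon unresolvable")
  if (subdivision_level < 1L) stop("subdivision_level must be >= 1")
  structure(list(subdivision_level = as.integer(subdivision_level),
                 white_radius = white_radius, pial_radius = pial_radius,
                 patch_center = patch_center / sqrt(sum(patch_center^2)),
                 patch_angular_radius = patch_angular_radius,
                 odi_background = odi_background, odi_patch = odi_patch,
                 fa_background = fa_background, fa_patch = fa_patch,
                 voxel_size = voxel_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Concentric white/pial icosphere pair
#'
#' Both meshes share vertex indexing and an identical triangle list; white
#' vertices sit at `white_radius` and pial vertices at `pial_radius` along
#' the same directions, so thickness is constant by construction.
#'
#' @param spec a `phantom_spec`.
#' @return a `surface_pair`.
#' @export
make_phantom_surfaces <- function(spec) {
  sph <- icosphere(spec$subdivision_level, radius = 1)
  surface_pair(white = sph$vertices * spec$white_radius,
               pial = sph$vertices * spec$pial_radius,
               triangles = sph$triangles)
}

#' Ground-truth patch vertex set
#'
#' Vertices whose mid-thickness point lies within `patch_angular_radius` of
#' the patch center — the exact ground truth against which recovered
#' parcels are Dice-scored.
#'
#' @param surfaces a `surface_pair`.
#' @param spec a `phantom_spec`.
#' @return integer vertex indices (1-based).
#' @export
patch_vertices <- function(surfaces, spec) {
  mid <- (surfaces$white + surfaces$pial) / 2
  which(angular_distance(mid, spec$patch_center) <= spec$patch_angular_radius)
}

#' Microstructure parameter phantom volumes
#'
#' Builds ODI and FA volumes on an isotropic grid fully containing the pial
#' sphere.  The parameter field is purely angular: every voxel within
#' `patch_angular_radius` of the patch center direction takes the patch
#' value and every other voxel the background value, so the field is
#' constant along the sampling rays through the cortical ribbon and
#' interpolation near the ribbon boundaries stays clean.  Optional additive
#' Gaussian noise (seeded) is clipped to (0, 1).
#'
#' @param spec a `phantom_spec`.
#' @param surfaces a `surface_pair` from [make_phantom_surfaces()] (used
#'   for consistency checks).
#' @return list with `odi` and `fa` (`scalar_volume`s on the same grid).
#' @export
make_microstructure_phantom <- function(spec, surfaces = NULL) {
  extent <- spec$pial_radius + 3 * spec$voxel_size
  n <- as.integer(ceiling(2 * extent / spec$voxel_size))
  origin <- -spec$voxel_size * (n - 1) / 2
  affine <- diag(c(rep(spec$voxel_size, 3), 1))
  affine[1:3, 4L] <- origin
  ax <- origin + spec$voxel_size * (0:(n - 1))
  X <- array(ax, c(n, n, n))
  Y <- aperm(X, c(2L, 1L, 3L))
  Z <- aperm(X, c(3L, 2L, 1L))
  r <- sqrt(X^2 + Y^2 + Z^2)
  cen <- spec$patch_center
  ct <- (X * cen[1L] + Y * cen[2L] + Z * cen[3L]) / pmax(r, 1e-12)
  in_patch <- acos(pmin(1, pmax(-1, ct))) <= spec$patch_angular_radius
  odi <- ifelse(in_patch, spec$odi_patch, spec$odi_background)
  fa <- ifelse(in_patch, spec$fa_patch, spec$fa_background)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    odi <- odi + rnorm(length(odi), sd = spec$noise_sd)
    fa <- fa + rnorm(length(fa), sd = spec$noise_sd)
  }
  clip <- function(v) pmin(pmax(v, 1e-6), 1 - 1e-6)
  list(odi = scalar_volume(array(clip(odi), c(n, n, n)), affine),
       fa = scalar_volume(array(clip(fa), c(n, n, n)), affine))
}

#' Multi-shell diffusion-weighted phantom signals
#'
#' Generates normalized signals from the NODDI forward model per voxel and
#' adds seeded Gaussian noise.  The mean b=0 signal is 1 before noise.
#'
#' @param params list with 3D arrays (or `scalar_volume`s) `ndi`, `odi`,
#'   `viso`, and optionally `mu` (either an N_voxel x 3 orientation matrix,
#'   a single unit 3-vector, or the default `"radial"` which orients
#'   neurites along the position vector from the volume center, as in a
#'   spherical cortical phantom).
#' @param protocol a `diffusion_protocol` (must contain a b=0 measurement).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @param mask optional logical array of voxels to simulate.
#' @return 4D array (x, y, z, measurement); unsimulated voxels are zero.
#' @export
make_dwi_phantom <- function(params, protocol, noise_sd = 0, seed = 1L,
                             mask = NULL) {
  grab <- function(p) if (inherits(p, "scalar_volume")) p$data else as.array(p)
  ndi <- grab(params$ndi); odi <- grab(params$odi); viso <- grab(params$viso)
  d <- dim(ndi)
  if (!identical(d, dim(odi)) || !identical(d, dim(viso)))
    stop("parameter volumes disagree in dimension")
  if (is.null(mask)) mask <- array(TRUE, d)
  n_meas <- length(protocol$bvals)
  sig <- array(0, c(d, n_meas))
  idx <- which(mask)
  ijk <- arrayInd(idx, d)
  mu <- params$mu
  if (is.null(mu)) mu <- "radial"
  flat <- matrix(sig, length(ndi), n_meas)
  for (m in seq_along(idx)) {
    v <- idx[m]
    mu_v <- if (is.character(mu)) {
      p <- ijk[m, ] - (d + 1) / 2
      if (sum(p^2) < 1e-9) c(0, 0, 1) else p / sqrt(sum(p^2))
    } else if (is.matrix(mu)) mu[m, ] else mu
    flat[v, ] <- noddi_forward(list(ndi = ndi[v], odi = odi[v],
                                    viso = viso[v], mu = mu_v), protocol)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    flat[idx, ] <- flat[idx, ] +
      rnorm(length(idx) * n_meas, sd = noise_sd)
  }
  array(flat, c(d, n_meas))
}

#' Twin/retest cohort specification
#'
#' ACE variance components of the simulated trait: additive genetic (`a2`),
#' shared environment (`c2`) and unique environment (`e2`), summing to 1.
#' MZ co-twins share the full additive and shared components; DZ co-twins
#' share half the additive and the full shared component; non-twin (NT)
#' siblings are generated with DZ-like genetic sharing but labeled
#' distinctly, mirroring how they are analyzed as a separate empirical
#' group.
#'
#' @param n_mz_pairs,n_dz_pairs,n_nt_pairs,n_singletons group sizes.
#' @param a2,c2,e2 variance fractions summing to 1.
#' @param retest_noise_sd measurement noise SD (same units as the trait,
#'   which has unit latent variance).
#' @param behavioral_beta standardized effect of the latent trait on the
#'   generated behavioral score.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mz_pairs = 140L, n_dz_pairs = 80L,
                        n_nt_pairs = 160L, n_singletons = 100L,
                        a2 = 0.5, c2 = 0.2, e2 = 0.3,
                        retest_noise_sd = 0.2, behavioral_beta = 0.15,
                        seed = 1L) {
  if (abs(a2 + c2 + e2 - 1) > 1e-8)
    stop("variance fractions a2 + c2 + e2 must sum to 1")
  if (any(c(a2, c2, e2) < 0)) stop("variance fractions must be >= 0")
  counts <- c(n_mz_pairs, n_dz_pairs, n_nt_pairs, n_singletons)
  if (any(counts < 0)) stop("counts must be >= 0")
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 n_nt_pairs = as.integer(n_nt_pairs),
                 n_singletons = as.integer(n_singletons),
                 a2 = a2, c2 = c2, e2 = e2,
                 retest_noise_sd = retest_noise_sd,
                 behavioral_beta = behavioral_beta, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a twin/retest cohort with known ACE structure
#'
#' Latent trait per subject: `sqrt(a2) A + sqrt(c2) C + sqrt(e2) E` with
#' standard-normal components; the observed metric adds measurement noise,
#' and the retest table is a second independent noisy draw of the same
#' latent trait.  A behavioral column is generated with standardized slope
#' `behavioral_beta` against the latent trait.  Expected pair correlations
#' of the latent trait are `a2 + c2` (MZ) and `a2/2 + c2` (DZ and NT).
#'
#' @param spec a `cohort_spec`.
#' @return list with `cohort` (data frame: `subject_id`, `mother_id`,
#'   `father_id`, `zygosity` in MZ/DZ/NT/SGL, `sex`, `age`, `metric`,
#'   `behavior`), `retest` (data frame: `subject_id`, `metric`) and
#'   `latent` (true trait values).
#' @export
make_cohort <- function(spec) {
  set.seed(spec$seed)
  groups <- rbind(
    data.frame(zyg = "MZ", n = spec$n_mz_pairs),
    data.frame(zyg = "DZ", n = spec$n_dz_pairs),
    data.frame(zyg = "NT", n = spec$n_nt_pairs),
    data.frame(zyg = "SGL", n = spec$n_singletons))
  subject <- character(); mother <- character(); father <- character()
  zyg <- character(); latent <- numeric()
  fam <- 0L; sid <- 0L
  for (g in seq_len(nrow(groups))) {
    for (i in seq_len(groups$n[g])) {
      fam <- fam + 1L
      zg <- groups$zyg[g]
      k <- if (zg == "SGL") 1L else 2L
      C <- rnorm(1L)
      if (zg == "MZ") {
        A <- rep(rnorm(1L), 2L)
      } else if (zg %in% c("DZ", "NT")) {
        A <- sqrt(0.5) * rnorm(1L) + sqrt(0.5) * rnorm(2L)
      } else {
        A <- rnorm(1L)
      }
      E <- rnorm(k)
      lat <- sqrt(spec$a2) * A[seq_len(k)] + sqrt(spec$c2) * C +
        sqrt(spec$e2) * E
      for (j in seq_len(k)) {
        sid <- sid + 1L
        subject <- c(subject, sprintf("S%05d", sid))
        mother <- c(mother, sprintf("M%05d", fam))
        father <- c(father, sprintf("F%05d", fam))
        zyg <- c(zyg, zg)
      }
      latent <- c(latent, lat)
    }
  }
  n <- length(latent)
  metric <- latent + rnorm(n, sd = spec$retest_noise_sd)
  retest <- latent + rnorm(n, sd = spec$retest_noise_sd)
  beta <- spec$behavioral_beta
  behavior <- beta * latent + sqrt(max(0, 1 - beta^2)) * rnorm(n)
  cohort <- data.frame(subject_id = subject, mother_id = mother,
                       father_id = father, zygosity = zyg,
                       sex = sample(c("M", "F"), n, replace = TRUE),
                       age = round(runif(n, 22, 36), 1),
                       metric = metric, behavior = behavior,
                       stringsAsFactors = FALSE)
  list(cohort = cohort,
       retest = data.frame(subject_id = subject, metric = retest,
                           stringsAsFactors = FALSE),
       latent = latent)
}

#' Synthetic cohort of surface maps with a planted optimal threshold
#'
#' Generates per-subject vertex ODI maps on a shared icosphere topology
#' whose parcel-volume distribution across the cohort is symmetric exactly
#' at the planted threshold `tau_star` and increasingly skewed away from
#' it.  Construction: each subject carries a fixed uniform score
#' `u = F(z)`; the target parcel volume at threshold tau is the `u`-quantile
#' of a scaled Beta distribution with shapes
#' `a = shape0 * exp(shape_gain (tau - tau_star))` and
#' `b = shape0 * exp(-shape_gain (tau - tau_star))`, which is symmetric
#' (skewness 0) at `tau = tau_star` and, because the Beta family is ordered
#' by convex transforms in this direction, has across-subject sample
#' skewness monotone in tau — a unique zero crossing at the planted
#' optimum.  The vertex map inverts this volume profile through the mesh's
#' empirical cap-volume function around the map center, so thresholding the
#' map at tau recovers the target volume up to vertex quantization.  Toward
#' the sweep extremes the volume distribution degenerates smoothly to
#' all-empty / all-full parcels (zero variance, skewness undefined and
#' excluded), with no saturation artifacts in between.
#'
#' Because the parcellation chain applies Laplacian smoothing before
#' thresholding, the returned maps are the pre-image of the designed
#' profile under the (linear) smoothing operator for the given
#' `smoothing` configuration: smoothing the maps reproduces the designed
#' field exactly, so the planted structure lives in the domain where the
#' threshold actually operates.
#'
#' @param n_subjects cohort size (default 40).
#' @param level icosphere subdivision level (default 4).
#' @param tau_star planted skewness-minimizing threshold (default 0.375).
#' @param shape0 Beta shape at the optimum (default 4; larger = tighter
#'   volume distribution).
#' @param shape_gain log-shape gain per unit threshold (default 30; larger
#'   = steeper skewness ramp around the optimum).
#' @param restriction_radius angular radius of the restriction mask
#'   (default 1.2 rad).
#' @param white_radius,pial_radius shell radii in mm.
#' @param smoothing the `smoothing_config` the parcellation chain will use
#'   (the maps are pre-inverted through this operator).
#' @param seed RNG seed.
#' @return list with `maps` (V x n_subjects matrix), `surfaces`,
#'   `adjacency`, `morphometry`, `restriction` (vertex indices),
#'   `tau_star`, `u` (subject quantile scores), `smoothing`.
#' @export
make_sweep_cohort <- function(n_subjects = 40L, level = 4L, tau_star = 0.375,
                              shape0 = 4, shape_gain = 30,
                              restriction_radius = 1.2, white_radius = 30,
                              pial_radius = 33,
                              smoothing = smoothing_config(), seed = 1L) {
  spec <- phantom_spec(subdivision_level = level, white_radius = white_radius,
                       pial_radius = pial_radius, seed = seed)
  surfaces <- make_phantom_surfaces(spec)
  adjacency <- mesh_adjacency(surfaces)
  morph <- vertex_morphometry(surfaces)
  theta <- angular_distance((surfaces$white + surfaces$pial) / 2, c(0, 0, 1))
  restriction <- which(theta <= restriction_radius)
  # empirical cap-volume function: cumulative vertex volume fraction by angle
  ord <- order(theta[restriction])
  cum <- cumsum(morph$volume[restriction][ord])
  cfrac <- numeric(length(restriction))
  cfrac[ord] <- cum / cum[length(cum)]
  set.seed(seed)
  u <- runif(n_subjects)
  qv <- function(tau, us) {
    # clamp the shape exponent: beyond |x| ~ 6 the quantile is degenerate
    # at vertex-granule resolution and extreme shapes only cost accuracy
    x <- pmin(pmax(shape_gain * (tau - tau_star), -6), 6)
    suppressWarnings(stats::qbeta(us, shape0 * exp(x), shape0 * exp(-x)))
  }
  maps <- matrix(1, nrow(surfaces$white), n_subjects)
  for (s in seq_len(n_subjects)) {
    tau_v <- numeric(length(cfrac))
    lo <- qv(0, u[s]); hi <- qv(1, u[s])
    for (m in seq_along(cfrac)) {
      cv <- cfrac[m]
      tau_v[m] <- if (cv <= lo) 1e-4 else if (cv >= hi) 1 - 1e-4 else
        uniroot(function(tau) qv(tau, u[s]) - cv,
                lower = 0, upper = 1, tol = 1e-9)$root
    }
    maps[restriction, s] <- tau_v
  }
  # pre-invert the smoothing operator so smoothed(maps) == designed profile
  if (smoothing$iterations > 0L) {
    lam <- smoothing$lambda
    n <- adjacency$n_vertices
    W <- adjacency$matrix / pmax(adjacency$degree, 1L)
    M <- (1 - lam) * Matrix::Diagonal(n) + lam * W
    S <- Reduce(`%*%`, rep(list(M), smoothing$iterations))
    maps <- as.matrix(Matrix::solve(S, maps))
  }
  list(maps = maps, surfaces = surfaces, adjacency = adjacency,
       morphometry = morph, restriction = restriction, tau_star = tau_star,
       u = u, smoothing = smoothing)
}
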