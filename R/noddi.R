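#' Orientation dispersion index from Watson concentration
#'
#' The NODDI orientation dispersion index maps the Watson concentration
#' parameter kappa to the unit interval: `odi = (2/pi) * atan(1/kappa)`.
#' Low ODI means tightly aligned neurites (kappa large); ODI -> 1 as the
#' orientation distribution approaches isotropy.
#'
#' @param kappa Watson concentration, > 0.
#' @return ODI in (0, 1).
#' @export
odi_from_kappa <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa <= 0)) stop("kappa must be > 0")
  (2 / pi) * atan(1 / kappa)
}

#' @rdname odi_from_kappa
#' @param odi orientation dispersion index in (0, 1).
#' @export
kappa_from_odi <- function(odi) {
  if (any(odi <= 0) || any(odi >= 1)) stop("odi must lie in (0, 1)")
  1 / tan(pi * odi / 2)
}

# Gauss-Legendre x uniform-azimuth quadrature nodes on the sphere, cached.
.sphere_quad <- local({
  cache <- list()
  function(n_theta = 48L, n_phi = 32L) {
    key <- paste(n_theta, n_phi)
    if (is.null(cache[[key]])) {
      gl <- pracma::gaussLegendre(n_theta, -1, 1)
      u <- rep(gl$x, each = n_phi)
      wu <- rep(gl$w, each = n_phi)
      phi <- rep(2 * pi * (seq_len(n_phi) - 1) / n_phi, times = n_theta)
      s <- sqrt(pmax(0, 1 - u^2))
      cache[[key]] <<- list(
        nodes = cbind(s * cos(phi), s * sin(phi), u),
        w = wu / n_phi,   # relative weights; normalized against the density
        u = u)
    }
    cache[[key]]
  }
})

# Watson weights over the quadrature nodes, normalized to sum 1.
# Mean axis is +z in the node frame.  exp(kappa*(u^2-1)) avoids overflow.
.watson_weights <- function(kappa, quad) {
  w <- quad$w * exp(kappa * (quad$u^2 - 1))
  w / sum(w)
}

#' NODDI forward model (Watson-dispersed stick + zeppelin + isotropic)
#'
#' Normalized signal
#' `S/S0 = (1 - v_iso) * (v_ic * A_ic + (1 - v_ic) * A_ec) + v_iso * exp(-b d_iso)`
#' where the intra-cellular response `A_ic` is a Watson-dispersed stick with
#' axial diffusivity `d_par`, and the extra-cellular response `A_ec` is a
#' Watson-dispersed zeppelin with tortuosity coupling
#' `d_perp = d_par * (1 - v_ic)`.  The orientation average is evaluated by
#' Gauss-Legendre quadrature over the sphere.
#'
#' @param params list with elements `ndi` (intra-cellular fraction v_ic),
#'   `odi`, `viso`, and optionally `mu` (unit mean orientation, default +z),
#'   `d_par` (default 1.1e-3 mm^2/s) and `d_iso` (default 3.0e-3 mm^2/s).
#' @param protocol a `diffusion_protocol`.
#' @param n_theta,n_phi quadrature resolution.
#' @return normalized signal, one value per measurement.
#' @export
noddi_forward <- function(params, protocol, n_theta = 48L, n_phi = 32L) {
  p <- .noddi_params(params)
  quad <- .sphere_quad(n_theta, n_phi)
  wts <- .watson_weights(p$kappa, quad)
  basis <- .orthobasis(p$mu)
  g_local <- protocol$bvecs %*% t(basis)          # gradients in mu frame
  dots2 <- (g_local %*% t(quad$nodes))^2          # n_meas x n_nodes
  b <- protocol$bvals
  d_perp <- p$d_par * (1 - p$ndi)
  a_ic <- as.vector(exp(-(b * p$d_par) * dots2) %*% wts)
  a_ec <- exp(-b * d_perp) *
    as.vector(exp(-(b * (p$d_par - d_perp)) * dots2) %*% wts)
  (1 - p$viso) * (p$ndi * a_ic + (1 - p$ndi) * a_ec) +
    p$viso * exp(-b * p$d_iso)
}

.noddi_params <- function(params) {
  p <- params
  if (is.null(p$mu)) p$mu <- c(0, 0, 1)
  if (is.null(p$d_par)) p$d_par <- 1.1e-3
  if (is.null(p$d_iso)) p$d_iso <- 3.0e-3
  stopifnot(p$ndi >= 0, p$ndi <= 1, p$viso >= 0, p$viso <= 1,
            p$odi > 0, p$odi < 1)
  p$mu <- p$mu / sqrt(sum(p$mu^2))
  p$kappa <- kappa_from_odi(p$odi)
  p
}

#' Per-shell spherical mean of a diffusion signal
#'
#' Arithmetic mean of the (normalized) signal over the gradient directions
#' of each shell.  The spherical mean is independent of the orientation
#' distribution, which is what makes it useful for accelerating the NODDI
#' fit: the per-shell means depend only on the compartment fractions.
#'
#' @param signal numeric vector, one value per measurement, normalized by
#'   the mean b=0 signal.
#' @param protocol a `diffusion_protocol`.
#' @return named numeric vector of shell means (names are nominal b-values,
#'   including the `"0"` shell).
#' @export
spherical_mean <- function(signal, protocol) {
  if (length(signal) != length(protocol$bvals))
    stop("signal length does not match protocol")
  vapply(protocol$shells, function(idx) mean(signal[idx]), numeric(1L))
}

# spherical mean of exp(-b*d*(g.n)^2) over directions g:
# sqrt(pi/(4 b d)) * erf(sqrt(b d))
.smt_kernel_mean <- function(bd) {
  out <- rep(1, length(bd))
  nz <- bd > 1e-12
  out[nz] <- sqrt(pi / (4 * bd[nz])) * pracma::erf(sqrt(bd[nz]))
  out
}

# model spherical means per shell for given fractions
.noddi_shell_means <- function(ndi, viso, b, d_par, d_iso) {
  d_perp <- d_par * (1 - ndi)
  m_ic <- .smt_kernel_mean(b * d_par)
  m_ec <- exp(-b * d_perp) * .smt_kernel_mean(b * (d_par - d_perp))
  (1 - viso) * (ndi * m_ic + (1 - ndi) * m_ec) + viso * exp(-b * d_iso)
}

#' Fit the NODDI model voxel-wise, accelerated by the spherical mean
#'
#' Two-stage fit.  Stage 1 estimates the intra-cellular and isotropic
#' fractions from the per-shell spherical means, which are free of
#' orientation parameters.  Stage 2 estimates the Watson concentration and
#' mean orientation (and refines the fractions) by bounded nonlinear least
#' squares on the full signal, initialized from stage 1 and from the
#' principal axis of a log-linear tensor fit.  ODI is derived from kappa.
#'
#' @param signal 4D array (x, y, z, measurement) or N x M matrix of signals.
#' @param protocol a `diffusion_protocol`.
#' @param mask logical array/vector of voxels to fit (default: all).
#' @param d_par fixed parallel diffusivity, mm^2/s (default 1.1e-3, the
#'   gray-matter-optimized value).
#' @param d_iso fixed isotropic diffusivity, mm^2/s (default 3.0e-3).
#' @param n_theta,n_phi quadrature resolution for the Watson average.
#' @param refit_fractions logical; refit v_ic and v_iso in stage 2
#'   (default TRUE).
#' @return list of arrays/vectors matching the input spatial shape:
#'   `ndi`, `odi`, `viso`, `kappa`, `mu` (N x 3 matrix of orientations) and
#'   `flag` (0 ok, 1 skipped non-finite/zero, 2 negligible signal decay).
#' @export
fit_noddi <- function(signal, protocol, mask = NULL,
                      d_par = 1.1e-3, d_iso = 3.0e-3,
                      n_theta = 48L, n_phi = 32L, refit_fractions = TRUE) {
  sh <- .signal_matrix(signal, protocol)
  S <- sh$S; spatial <- sh$spatial
  n_vox <- nrow(S)
  if (is.null(mask)) mask <- rep(TRUE, n_vox)
  mask <- as.logical(mask)
  b <- protocol$bvals
  shell_b <- as.numeric(names(protocol$shells))
  out <- list(ndi = rep(NA_real_, n_vox), odi = rep(NA_real_, n_vox),
              viso = rep(NA_real_, n_vox), kappa = rep(NA_real_, n_vox),
              mu = matrix(NA_real_, n_vox, 3L), flag = integer(n_vox))
  quad <- .sphere_quad(n_theta, n_phi)

  for (v in which(mask)) {
    s <- S[v, ]
    if (any(!is.finite(s)) || all(s == 0)) { out$flag[v] <- 1L; next }
    s0 <- mean(s[protocol$b0])
    if (s0 <= 0) { out$flag[v] <- 1L; next }
    sn <- s / s0
    sm <- spherical_mean(sn, protocol)
    if (min(sm) > 0.98) { out$flag[v] <- 2L; next }  # no measurable decay

    # stage 1: fractions from shell means (coarse grid + refine)
    st1 <- .fit_smt_fractions(sm, shell_b, d_par, d_iso)
    # orientation init: principal axis of a log-linear tensor fit
    mu0 <- .tensor_principal_axis(sn, protocol)
    fit <- .fit_noddi_stage2(sn, protocol, st1, mu0, d_par, d_iso, quad,
                             refit_fractions)
    out$ndi[v] <- fit$ndi; out$odi[v] <- fit$odi; out$viso[v] <- fit$viso
    out$kappa[v] <- kappa_from_odi(fit$odi)
    out$mu[v, ] <- fit$mu
  }
  .reshape_fit(out, spatial)
}

.signal_matrix <- function(signal, protocol) {
  if (is.array(signal) && length(dim(signal)) == 4L) {
    spatial <- dim(signal)[1:3]
    S <- matrix(signal, prod(spatial), dim(signal)[4L])
  } else {
    S <- as.matrix(signal)
    spatial <- NULL
  }
  if (ncol(S) != length(protocol$bvals))
    stop("signal measurement count does not match protocol")
  list(S = S, spatial = spatial)
}

.reshape_fit <- function(out, spatial) {
  if (!is.null(spatial)) {
    for (nm in c("ndi", "odi", "viso", "kappa"))
      out[[nm]] <- array(out[[nm]], spatial)
    out$flag <- array(out$flag, spatial)
  }
  out
}

.fit_smt_fractions <- function(sm, shell_b, d_par, d_iso) {
  obj <- function(p) {
    sum((sm - .noddi_shell_means(p[1L], p[2L], shell_b, d_par, d_iso))^2)
  }
  grid <- as.matrix(expand.grid(ndi = seq(0.02, 0.98, by = 0.06),
                                viso = seq(0.02, 0.98, by = 0.06)))
  vals <- apply(grid, 1L, obj)
  p0 <- grid[which.min(vals), ]
  opt <- optim(p0, obj, method = "L-BFGS-B",
               lower = c(0, 0), upper = c(1, 1),
               control = list(maxit = 200, factr = 1e4))
  list(ndi = opt$par[1L], viso = opt$par[2L])
}

.tensor_principal_axis <- function(sn, protocol) {
  X <- .dti_design(protocol)
  y <- log(pmax(sn, 1e-6))
  beta <- tryCatch(qr.solve(X, y), error = function(e) NULL)
  if (is.null(beta)) return(c(0, 0, 1))
  D <- matrix(c(beta[2L], beta[5L], beta[6L],
                beta[5L], beta[3L], beta[7L],
                beta[6L], beta[7L], beta[4L]), 3L, 3L)
  ev <- eigen(D, symmetric = TRUE)
  ev$vectors[, 1L]
}

.fit_noddi_stage2 <- function(sn, protocol, st1, mu0, d_par, d_iso, quad,
                              refit_fractions) {
  sph <- c(acos(pmin(1, pmax(-1, mu0[3L]))), atan2(mu0[2L], mu0[1L]))
  fwd <- function(p) {
    mu <- c(sin(p[4L]) * cos(p[5L]), sin(p[4L]) * sin(p[5L]), cos(p[4L]))
    wts <- .watson_weights(kappa_from_odi(p[3L]), quad)
    basis <- .orthobasis(mu)
    dots2 <- (protocol$bvecs %*% t(basis) %*% t(quad$nodes))^2
    b <- protocol$bvals
    d_perp <- d_par * (1 - p[1L])
    a_ic <- as.vector(exp(-(b * d_par) * dots2) %*% wts)
    a_ec <- exp(-b * d_perp) *
      as.vector(exp(-(b * (d_par - d_perp)) * dots2) %*% wts)
    (1 - p[2L]) * (p[1L] * a_ic + (1 - p[1L]) * a_ec) +
      p[2L] * exp(-b * d_iso)
  }
  p0 <- c(st1$ndi, st1$viso, 0.3, sph)
  lower <- c(0, 0, 0.01, -Inf, -Inf)
  upper <- c(1, 1, 0.99, Inf, Inf)
  if (!refit_fractions) {
    resid <- function(q) sn - fwd(c(st1$ndi, st1$viso, q))
    fit <- minpack.lm::nls.lm(par = p0[3:5], lower = lower[3:5],
                              upper = upper[3:5], fn = resid,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200, ftol = 1e-8, ptol = 1e-8))
    p <- c(st1$ndi, st1$viso, fit$par)
  } else {
    resid <- function(p) sn - fwd(p)
    fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                              fn = resid,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200, ftol = 1e-8, ptol = 1e-8))
    p <- fit$par
  }
  mu <- c(sin(p[4L]) * cos(p[5L]), sin(p[4L]) * sin(p[5L]), cos(p[4L]))
  list(ndi = p[1L], viso = p[2L], odi = p[3L], mu = mu)
}
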