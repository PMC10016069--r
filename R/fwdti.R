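#' Fractional anisotropy and mean diffusivity from tensor eigenvalues
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`;
#' `MD = mean(lambda)`.  Small negative eigenvalues (noise) are clamped to
#' zero first; an all-zero tensor has FA defined as 0.
#'
#' @param eigenvalues numeric length-3 (or N x 3 matrix), mm^2/s.
#' @return list with `fa` and `md` (vectors for matrix input).
#' @export
fa_md <- function(eigenvalues) {
  ev <- if (is.matrix(eigenvalues)) eigenvalues else matrix(eigenvalues, 1L)
  ev <- pmax(ev, 0)
  md <- rowMeans(ev)
  num <- sqrt(rowSums((ev - md)^2))
  den <- sqrt(rowSums(ev^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  list(fa = as.vector(fa), md = as.vector(md))
}

# DTI log-linear design: columns (1, -b gx^2, -b gy^2, -b gz^2,
# -2b gx gy, -2b gx gz, -2b gy gz)
.dti_design <- function(protocol) {
  g <- protocol$bvecs; b <- protocol$bvals
  cbind(1, -b * g[, 1L]^2, -b * g[, 2L]^2, -b * g[, 3L]^2,
        -2 * b * g[, 1L] * g[, 2L], -2 * b * g[, 1L] * g[, 3L],
        -2 * b * g[, 2L] * g[, 3L])
}

.d6_to_matrix <- function(d6) {
  matrix(c(d6[1L], d6[4L], d6[5L],
           d6[4L], d6[2L], d6[6L],
           d6[5L], d6[6L], d6[3L]), 3L, 3L)
}

# quadratic form g' D g for all measurements, d6 = (xx, yy, zz, xy, xz, yz)
.tensor_adc <- function(d6, g) {
  g[, 1L]^2 * d6[1L] + g[, 2L]^2 * d6[2L] + g[, 3L]^2 * d6[3L] +
    2 * g[, 1L] * g[, 2L] * d6[4L] + 2 * g[, 1L] * g[, 3L] * d6[5L] +
    2 * g[, 2L] * g[, 3L] * d6[6L]
}

#' Free-water DTI forward model
#'
#' `S/S0 = (1 - f) * exp(-b g' D g) + f * exp(-b d_iso)`.
#'
#' @param d6 tissue tensor as (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), mm^2/s.
#' @param f free-water fraction in `[0, 1]`.
#' @param protocol a `diffusion_protocol`.
#' @param d_iso fixed free-water diffusivity (default 3.0e-3 mm^2/s).
#' @return normalized signal per measurement.
#' @export
fwdti_forward <- function(d6, f, protocol, d_iso = 3.0e-3) {
  b <- protocol$bvals
  (1 - f) * exp(-b * .tensor_adc(d6, protocol$bvecs)) + f * exp(-b * d_iso)
}

#' Fit the free-water-eliminated diffusion tensor voxel-wise
#'
#' The tissue tensor is initialized by weighted linear least squares on the
#' log-signal (weights = squared predicted signal, two passes), then the
#' two-compartment model `S/S0 = (1 - f) exp(-b g' D g) + f exp(-b d_iso)`
#' is fit by bounded nonlinear least squares with the free-water fraction
#' constrained to `[0, 1]`, a fixed isotropic diffusivity, and tissue
#' diffusivities bounded below the free-water diffusivity (which keeps the
#' two compartments identifiable).  FA and MD are derived from the tissue
#' tensor eigenvalues (negatives clamped to zero).
#'
#' @inheritParams fit_noddi
#' @param d_iso fixed free-water diffusivity, mm^2/s (default 3.0e-3).
#' @return list of arrays/vectors: `fa`, `md`, `f`, `tensor` (N x 6),
#'   `flag` (0 ok, 1 skipped, 3 tensor unreliable because f > 0.95).
#' @export
fit_fwdti <- function(signal, protocol, mask = NULL, d_iso = 3.0e-3) {
  sh <- .signal_matrix(signal, protocol)
  S <- sh$S; spatial <- sh$spatial
  n_vox <- nrow(S)
  if (is.null(mask)) mask <- rep(TRUE, n_vox)
  mask <- as.logical(mask)
  X <- .dti_design(protocol)
  if (qr(X)$rank < 7L)
    stop("rank-deficient diffusion design: need >= 6 unique gradient ",
         "directions plus b=0")
  out <- list(fa = rep(NA_real_, n_vox), md = rep(NA_real_, n_vox),
              f = rep(NA_real_, n_vox),
              tensor = matrix(NA_real_, n_vox, 6L), flag = integer(n_vox))
  b <- protocol$bvals
  for (v in which(mask)) {
    s <- S[v, ]
    if (any(!is.finite(s)) || all(s == 0)) { out$flag[v] <- 1L; next }
    s0 <- mean(s[protocol$b0])
    if (s0 <= 0) { out$flag[v] <- 1L; next }
    sn <- pmax(s / s0, 1e-6)
    d6 <- .fit_dti_wlls(sn, X)
    resid <- function(p) sn - fwdti_forward(p[2:7], p[1L], protocol, d_iso)
    # tissue diffusivities are bounded below the free-water diffusivity,
    # which keeps the two compartments identifiable (a pure-CSF voxel is
    # otherwise equally well explained by f = 0 and an isotropic tensor
    # at d_iso)
    dmax <- 0.97 * d_iso
    lower <- c(0, 0, 0, 0, -dmax, -dmax, -dmax)
    upper <- c(1, dmax, dmax, dmax, dmax, dmax, dmax)
    fit <- minpack.lm::nls.lm(
      par = pmin(pmax(c(0.05, d6), lower + 1e-9), upper - 1e-9),
      lower = lower, upper = upper,
      fn = resid,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-8,
                                           ptol = 1e-8))
    f <- fit$par[1L]
    d6 <- fit$par[2:7]
    ev <- eigen(.d6_to_matrix(d6), symmetric = TRUE, only.values = TRUE)$values
    fm <- fa_md(ev)
    out$fa[v] <- fm$fa; out$md[v] <- fm$md; out$f[v] <- f
    out$tensor[v, ] <- d6
    if (f > 0.95) out$flag[v] <- 3L
  }
  if (!is.null(spatial)) {
    for (nm in c("fa", "md", "f")) out[[nm]] <- array(out[[nm]], spatial)
    out$flag <- array(out$flag, spatial)
  }
  out
}

# weighted linear least squares tensor fit on the log signal (two passes)
.fit_dti_wlls <- function(sn, X) {
  y <- log(sn)
  beta <- qr.solve(X, y)
  for (pass in 1:2) {
    w <- exp(X %*% beta)^2
    beta <- qr.solve(X * sqrt(as.vector(w)), y * sqrt(as.vector(w)))
  }
  c(beta[2L], beta[3L], beta[4L], beta[5L], beta[6L], beta[7L])
}
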