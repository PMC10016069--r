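test_that("ODI <-> kappa mapping matches its closed form and limits", {
  expect_equal(odi_from_kappa(1), 0.5)
  expect_lt(odi_from_kappa(1e6), 1e-5)
  expect_gt(odi_from_kappa(1e-6), 1 - 1e-5)
  odis <- c(0.01, 0.1, 0.3, 0.5, 0.9, 0.99)
  expect_equal(odi_from_kappa(kappa_from_odi(odis)), odis, tolerance = 1e-12)
  expect_error(odi_from_kappa(0), "kappa")
  expect_error(kappa_from_odi(1), "odi")
})

test_that("spherical mean matches closed forms and is kappa-independent", {
  prot <- small_protocol()
  # constant signal
  expect_equal(unname(spherical_mean(rep(1, length(prot$bvals)), prot)),
               rep(1, 4))
  # isotropic decay
  d <- 1.5e-3
  m <- spherical_mean(exp(-prot$bvals * d), prot)
  expect_equal(unname(m), exp(-c(0, 1000, 2000, 3000) * d), tolerance = 1e-12)
  # Watson-dispersed stick: shell mean is independent of kappa and
  # orientation, and equals sqrt(pi/(4bd)) erf(sqrt(bd))
  b <- c(1000, 2000, 3000); dpar <- 1.1e-3
  analytic <- sqrt(pi / (4 * b * dpar)) * pracma::erf(sqrt(b * dpar))
  for (p in list(list(odi = 0.05, mu = c(0, 0, 1)),
                 list(odi = 0.5, mu = c(1, 0, 0)),
                 list(odi = 0.9, mu = c(1, 1, 1)))) {
    sig <- noddi_forward(list(ndi = 1, odi = p$odi, viso = 0, mu = p$mu), prot)
    sm <- spherical_mean(sig, prot)
    expect_equal(unname(sm[2:4]), analytic, tolerance = 1e-3)
  }
})

test_that("NODDI forward model honors its closed-form special cases", {
  prot <- small_protocol()
  s <- noddi_forward(list(ndi = 0.6, odi = 0.3, viso = 0.1), prot)
  expect_equal(unname(s[prot$b0]), rep(1, sum(prot$b0)), tolerance = 1e-12)
  # pure free water
  s_iso <- noddi_forward(list(ndi = 0.5, odi = 0.5, viso = 1), prot)
  expect_equal(unname(s_iso), exp(-prot$bvals * 3e-3), tolerance = 1e-12)
  # nearly undispersed stick along the gradient
  g1 <- which(!prot$b0)[1]
  mu <- prot$bvecs[g1, ]
  s_stick <- noddi_forward(list(ndi = 1, odi = 0.005, viso = 0, mu = mu), prot)
  expect_equal(s_stick[g1], exp(-prot$bvals[g1] * 1.1e-3), tolerance = 0.02)
})

test_that("NODDI fit recovers noiseless forward parameters", {
  prot <- small_protocol()
  cases <- expand.grid(ndi = c(0.3, 0.7), odi = c(0.15, 0.5), viso = c(0, 0.2))
  sig <- t(apply(cases, 1, function(p)
    noddi_forward(list(ndi = p[1], odi = p[2], viso = p[3],
                       mu = c(0.3, -0.5, 0.81)), prot)))
  fit <- fit_noddi(sig, prot)
  expect_true(all(abs(fit$ndi - cases$ndi) < 0.02))
  expect_true(all(abs(fit$odi - cases$odi) < 0.02))
  expect_true(all(abs(fit$viso - cases$viso) < 0.02))
  expect_true(all(fit$ndi >= 0 & fit$ndi <= 1))
  expect_true(all(fit$viso >= 0 & fit$viso <= 1))
})

test_that("NODDI fit handles degenerate voxels without crashing", {
  prot <- small_protocol()
  sig_iso <- noddi_forward(list(ndi = 0.5, odi = 0.5, viso = 1), prot)
  fit <- fit_noddi(rbind(sig_iso,
                         rep(1, length(prot$bvals)),       # no decay
                         rep(NA_real_, length(prot$bvals)), # non-finite
                         rep(0, length(prot$bvals))), prot) # all-zero
  expect_gte(fit$viso[1], 0.95)
  expect_equal(fit$flag[2], 2L)   # flagged: negligible decay
  expect_equal(fit$flag[3], 1L)   # skipped
  expect_equal(fit$flag[4], 1L)
  expect_true(all(is.na(fit$odi[2:4])))
})

test_that("fits are invariant to a global rotation of gradients", {
  prot <- small_protocol()
  set.seed(11)
  R <- random_rotation()
  mu <- c(0.2, 0.6, 0.77); mu <- mu / sqrt(sum(mu^2))
  sig <- noddi_forward(list(ndi = 0.6, odi = 0.25, viso = 0.05, mu = mu), prot)
  prot_rot <- diffusion_protocol(prot$bvals, prot$bvecs %*% t(R))
  sig_rot <- noddi_forward(list(ndi = 0.6, odi = 0.25, viso = 0.05,
                                mu = as.vector(R %*% mu)), prot_rot)
  expect_equal(sig, sig_rot, tolerance = 1e-9)
  f1 <- fit_noddi(matrix(sig, 1), prot)
  f2 <- fit_noddi(matrix(sig_rot, 1), prot_rot)
  expect_equal(f1$odi, f2$odi, tolerance = 1e-6)
  expect_equal(f1$ndi, f2$ndi, tolerance = 1e-6)
  d6 <- c(1.5e-3, 0.4e-3, 0.3e-3, 1e-4, -5e-5, 2e-5)
  sfw <- fwdti_forward(d6, 0.1, prot)
  D <- ficmap:::.d6_to_matrix(d6)
  Dr <- R %*% D %*% t(R)
  sfw_rot <- fwdti_forward(c(diag(Dr), Dr[1, 2], Dr[1, 3], Dr[2, 3]),
                           0.1, prot_rot)
  g1 <- fit_fwdti(matrix(sfw, 1), prot)
  g2 <- fit_fwdti(matrix(sfw_rot, 1), prot_rot)
  expect_equal(g1$fa, g2$fa, tolerance = 1e-6)
  expect_equal(g1$md, g2$md, tolerance = 1e-9)
})

test_that("FA and MD follow their defining formulas", {
  expect_equal(fa_md(c(1, 1, 1))$fa, 0)
  expect_equal(fa_md(c(1, 0, 0))$fa, 1)
  ev <- c(1.7, 0.2, 0.2) * 1e-3
  oracle <- sqrt(1.5) * sqrt(sum((ev - mean(ev))^2)) / sqrt(sum(ev^2))
  expect_equal(fa_md(ev)$fa, oracle, tolerance = 1e-12)
  expect_equal(fa_md(ev)$md, mean(ev))
  expect_equal(fa_md(c(0, 0, 0))$fa, 0)
  # negative eigenvalues are clamped
  expect_equal(fa_md(c(1, -0.1, 0))$fa, 1)
})

test_that("free-water DTI fit recovers noiseless tensors and fractions", {
  prot <- small_protocol()
  d6 <- c(1.7e-3, 0.2e-3, 0.2e-3, 0, 0, 0)
  true_fa <- fa_md(c(1.7, 0.2, 0.2) * 1e-3)$fa
  for (f in c(0, 0.2, 0.4)) {
    sig <- fwdti_forward(d6, f, prot)
    fit <- fit_fwdti(matrix(sig, 1), prot)
    expect_equal(fit$fa, true_fa, tolerance = 0.01)
    expect_equal(fit$f, f, tolerance = 0.02)
    expect_equal(fit$md * 1e3, 0.7, tolerance = 0.01)
  }
  # isotropic tensor
  sig_iso <- fwdti_forward(c(rep(0.8e-3, 3), 0, 0, 0), 0, prot)
  expect_lt(fit_fwdti(matrix(sig_iso, 1), prot)$fa, 0.01)
  # pure free water: fraction recovered, tensor flagged unreliable
  sig_fw <- exp(-prot$bvals * 3e-3)
  fw <- fit_fwdti(matrix(sig_fw, 1), prot)
  expect_gte(fw$f, 0.95)
  expect_equal(fw$flag[1], 3L)
})

test_that("rank-deficient diffusion designs are rejected", {
  bv <- rbind(c(0, 0, 0), matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE))
  prot <- diffusion_protocol(c(0, rep(1000, 5)), bv)
  expect_error(fit_fwdti(matrix(1, 1, 6), prot), "rank-deficient")
})
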