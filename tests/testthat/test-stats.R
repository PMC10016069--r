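test_that("threshold sweep produces the 41-point grid with monotone volumes", {
  sc <- make_sweep_cohort(n_subjects = 8, level = 3, seed = 2)
  sw <- sweep_thresholds(sc$maps, sc$adjacency, sc$morphometry,
                         sc$restriction, direction = "below")
  expect_identical(length(sw$thresholds), 41L)
  expect_equal(sw$thresholds, seq(0, 1, by = 0.025))
  expect_true(all(sw$volumes >= 0))
  # largest-component extraction aside, volumes are non-decreasing per
  # subject; on these nested cap maps the parcel is a single cap, so
  # monotonicity holds exactly
  for (s in seq_len(nrow(sw$volumes)))
    expect_true(all(diff(sw$volumes[s, ]) >= -1e-9))
})

test_that("threshold selection minimizes absolute skewness with lower ties", {
  sw <- structure(list(thresholds = seq(0, 1, by = 0.025),
                       skewness = rep(NA_real_, 41)), class = "sweep_result")
  sw$skewness[c(10, 20, 30)] <- c(0.4, -0.2, 0.9)
  expect_equal(select_threshold(sw), sw$thresholds[20])
  sw$skewness[c(12, 25)] <- c(0.2, -0.2)   # symmetric tie with index 20
  expect_equal(select_threshold(sw), sw$thresholds[12])
  sw$skewness[] <- NA
  expect_error(select_threshold(sw), "skewness")
})

test_that("ICC and CoV follow the mean-squares decomposition", {
  x <- c(1, 2, 3, 4)
  r <- reliability(x, x)
  expect_equal(r$icc, 1)
  expect_equal(r$cov, 0)
  # no between-subject signal: ICC degenerates to -1
  set.seed(6)
  noise <- rnorm(100)
  r2 <- reliability(noise, -noise + 2 * mean(noise))
  expect_lt(r2$icc, 0)
  # zero total variance is flagged undefined
  r3 <- reliability(rep(2, 5), rep(2, 5))
  expect_true(r3$undefined)
  expect_true(is.na(r3$icc))
  # 3:1 variance ratio: one-way ICC(1) is (MSB - MSW)/(MSB + MSW) -> 0.75
  set.seed(7)
  n <- 500
  subj <- rnorm(n, sd = sqrt(3))
  r4 <- reliability(subj + rnorm(n), subj + rnorm(n))
  expect_equal(r4$icc, 0.75, tolerance = 0.05)
  # equivalence with the classical one-way ICC(1) from an ANOVA table
  df <- data.frame(y = c(subj + rnorm(n), subj + rnorm(n)),
                   id = factor(rep(seq_len(n), 2)))
  ms <- anova(aov(y ~ id, df))$`Mean Sq`
  r5 <- reliability(df$y[seq_len(n)], df$y[n + seq_len(n)])
  expect_equal(r5$icc, (ms[1] - ms[2]) / (ms[1] + ms[2]), tolerance = 1e-10)
})

test_that("double-entry pair correlation is order-invariant and unbiased", {
  x <- c(1, 2, 3, 4, 5); y <- x
  expect_equal(pair_correlation(x, y), 1)
  set.seed(8)
  a <- rnorm(300); b <- 0.6 * a + rnorm(300, sd = 0.8)
  r1 <- pair_correlation(a, b)
  flip <- runif(300) < 0.5
  a2 <- ifelse(flip, b, a); b2 <- ifelse(flip, a, b)
  expect_equal(pair_correlation(a2, b2), r1, tolerance = 1e-12)
  # independent pairs: near-zero correlation
  expect_lt(abs(pair_correlation(rnorm(2000), rnorm(2000))), 0.05)
  expect_true(is.na(pair_correlation(rep(1, 5), rep(1, 5))))
})

test_that("Falconer's formula reproduces the worked examples", {
  expect_equal(falconer(0.61, 0.35), 0.52, tolerance = 1e-12)
  expect_equal(falconer(0.60, 0.39), 0.42, tolerance = 1e-12)
  expect_equal(falconer(0.4, 0.4), 0)
  expect_error(falconer(1.2, 0), "correlations")
})

test_that("sibling pairing matches parents and enumerates large sibships", {
  co <- data.frame(
    subject_id = paste0("S", 1:7),
    mother_id = c("m1", "m1", "m2", "m2", "m2", "m3", "m4"),
    father_id = c("f1", "f1", "f2", "f2", "f2", "f3", "f4"),
    zygosity = c("MZ", "MZ", "NT", "NT", "NT", "DZ", "DZ"),
    metric = c(1, 1.1, 2, 2.2, 2.4, 3, 9))
  p <- sibling_pairs(co, "metric")
  expect_equal(nrow(p$mz), 1)
  expect_equal(nrow(p$nt), 3)    # all unordered pairs of the 3-sibship
  expect_equal(nrow(p$dz), 0)    # different parents, no pair
})

test_that("group comparisons handle paired, unpaired and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  r <- compare_groups(x, x, paired = TRUE)
  expect_equal(r$t, 0)
  # constant nonzero difference: direction reported, p underflows
  r2 <- compare_groups(x + 2, x, paired = TRUE)
  expect_true(r2$undefined)
  expect_equal(r2$p, 0)
  expect_equal(sign(r2$estimate), 1)
  set.seed(10)
  a <- rnorm(200); b <- rnorm(200) + 0.5
  r3 <- compare_groups(a, b)
  expect_lt(r3$p, 0.01)
  expect_lt(r3$estimate, 0)
})

test_that("Tukey fences match direct quantile computation", {
  expect_true(all(tukey_filter(rep(5, 10))))
  x <- c(1:20, 1000)
  keep <- tukey_filter(x)
  expect_false(keep[21])
  expect_true(all(keep[1:20]))
  # oracle: direct fence computation
  set.seed(11)
  y <- c(rnorm(50), 12, -9)
  q <- quantile(y, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
  expect_identical(tukey_filter(y), y >= fence[1] & y <= fence[2])
})

test_that("standardized regression recovers slopes, R2 and delta-BIC", {
  set.seed(12)
  n <- 1000
  d <- data.frame(x = rnorm(n))
  d$y <- d$x
  # perfect fit: lm warns that the summary may be unreliable, by design here
  r <- suppressWarnings(regress_behavior(d, "y", "x"))
  expect_equal(r$std_beta, 1, tolerance = 1e-10)
  expect_equal(r$r2, 1, tolerance = 1e-10)
  # single standardized predictor, no excluded rows: std beta equals the
  # Pearson correlation exactly (tail-free uniforms keep Tukey inactive)
  du <- data.frame(x = runif(n)); du$y <- 0.5 * du$x + runif(n)
  ru <- regress_behavior(du, "y", "x")
  expect_equal(ru$std_beta, cor(du$y, du$x), tolerance = 1e-10)
  # generative slope recovery under Gaussian noise
  d2 <- data.frame(x = rnorm(n)); d2$y <- 0.3 * d2$x + rnorm(n)
  r2 <- regress_behavior(d2, "y", "x")
  expect_lt(abs(r2$std_beta - 0.3), 3 * r2$se)
  # covariates and collinearity
  d2$z <- rnorm(n); d2$z2 <- d2$z
  r3 <- regress_behavior(d2, "y", "x", covariates = "z")
  expect_true(is.finite(r3$delta_bic))
  expect_error(regress_behavior(d2, "y", "x", covariates = c("z", "z2")),
               "collinear")
})

test_that("a pure-noise predictor is penalized by BIC", {
  set.seed(13)
  n <- 1000
  neg <- vapply(seq_len(200), function(i) {
    d <- data.frame(y = rnorm(n), x = rnorm(n))
    regress_behavior(d, "y", "x")$delta_bic < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
})

test_that("BH q-values and rejections match the step-up definition", {
  r <- fdr_bh(0.01)
  expect_equal(r$q_values, 0.01)
  expect_true(r$reject)
  m <- 30
  r2 <- fdr_bh(rep(0.04, m))
  expect_true(all(r2$reject))   # 0.04 <= (m/m) * 0.05
  set.seed(14)
  for (i in 1:25) {
    p <- runif(sample(5:50, 1))^sample(1:3, 1)
    got <- fdr_bh(p)
    expect_identical(got$reject, bh_bruteforce(p, 0.05))
    expect_true(all(diff(sort(got$q_values)) >= -1e-15))
    expect_true(all(got$q_values >= p))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "p-values")
})

test_that("probability maps are subject fractions", {
  masks <- cbind(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  expect_equal(probability_map(masks), c(1, 0.5, 0))
  expect_equal(probability_map(list(masks[, 1], masks[, 1])),
               as.numeric(masks[, 1]))
  expect_error(probability_map(list(c(TRUE), c(TRUE, FALSE))), "topology")
})
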