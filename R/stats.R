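#' Adjusted Fisher-Pearson sample skewness
#'
#' `G1 = g1 * sqrt(n (n-1)) / (n - 2)` with `g1 = m3 / m2^(3/2)`.
#' Undefined (`NA`) for fewer than 3 values or zero variance.
#'
#' @param x numeric vector.
#' @return scalar skewness, `NA` when undefined.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Cohort threshold sweep for FI segmentation
#'
#' Runs the full parcellation chain (smoothing once per subject, then
#' thresholding, mode filtering, largest component, metrics) for every
#' candidate threshold from 0 to 1 in increments of 0.025 (41 thresholds),
#' and records the across-subject distribution of parcel volumes and its
#' adjusted Fisher-Pearson skewness per threshold.  Thresholds where the
#' volume distribution is degenerate (zero variance, e.g. all parcels
#' empty) get `NA` skewness.
#'
#' @param maps V x S matrix (or list of per-vertex vectors) of subject
#'   microstructure maps on a shared topology.
#' @param adjacency a `mesh_adjacency`.
#' @param morphometry a `vertex_morphometry` shared by the cohort, or a
#'   list of per-subject `vertex_morphometry` tables.
#' @param restriction vertex indices or logical restriction mask.
#' @param direction `"below"` (ODI) or `"above"` (FA).
#' @param smoothing a `smoothing_config`.
#' @param thresholds candidate thresholds (default `seq(0, 1, 0.025)`).
#' @param mode_iterations mode-filter passes (default 1).
#' @return object of class `sweep_result`: `thresholds`, `volumes`
#'   (S x n_thresholds), `skewness` (per threshold).
#' @export
sweep_thresholds <- function(maps, adjacency, morphometry, restriction,
                             direction = c("below", "above"),
                             smoothing = smoothing_config(),
                             thresholds = seq(0, 1, by = 0.025),
                             mode_iterations = 1L) {
  direction <- match.arg(direction)
  if (is.list(maps) && !is.matrix(maps)) maps <- do.call(cbind, maps)
  S <- ncol(maps)
  if (S < 3L) stop("threshold sweep needs at least 3 subjects")
  per_subject_morph <- is.list(morphometry) &&
    !inherits(morphometry, "vertex_morphometry")
  sm <- apply(maps, 2L, laplacian_smooth, adjacency = adjacency,
              config = smoothing)
  vols <- matrix(NA_real_, S, length(thresholds))
  for (s in seq_len(S)) {
    morph <- if (per_subject_morph) morphometry[[s]] else morphometry
    for (ti in seq_along(thresholds)) {
      m <- threshold_mask(sm[, s], thresholds[ti], direction, restriction)
      m <- mode_filter(m, adjacency, mode_iterations)
      m <- largest_component(m, adjacency, area = morph$area)
      vols[s, ti] <- sum(morph$volume[m])
    }
  }
  skew <- apply(vols, 2L, sample_skewness)
  structure(list(thresholds = thresholds, volumes = vols, skewness = skew),
            class = "sweep_result")
}

#' Select the skewness-minimizing threshold
#'
#' Returns the candidate threshold whose across-subject volume distribution
#' has the smallest absolute skewness; ties go to the lower threshold.
#'
#' @param sweep a `sweep_result`.
#' @return scalar threshold.
#' @export
select_threshold <- function(sweep) {
  a <- abs(sweep$skewness)
  if (all(is.na(a))) stop("no threshold with defined skewness")
  sweep$thresholds[which.min(a)]  # which.min skips NA, first = lowest
}

#' Test-retest reliability: ICC and CoV
#'
#' One-way decomposition over subjects with two sessions each.  With
#' between-subject and within-subject mean squares MSB and MSW,
#' `ICC = (MSB - MSW) / (MSB + MSW)` — for two sessions this is exactly the
#' classical one-way random-effects ICC(1) — and
#' `CoV = sqrt(MSW) / mean`, the within-subject SD over the grand mean.
#'
#' @param test,retest paired numeric vectors, one value per subject and
#'   session.
#' @return object of class `reliability_result`: `icc`, `cov`, `mu`,
#'   `sigma_between` (MSB), `sigma_within` (MSW), `undefined` flag (TRUE
#'   when the data have no variance at all).
#' @export
reliability <- function(test, retest) {
  if (length(test) != length(retest)) stop("test/retest must be paired")
  ok <- is.finite(test) & is.finite(retest)
  x <- test[ok]; y <- retest[ok]
  n <- length(x)
  if (n < 3L) stop("reliability needs at least 3 subjects")
  m_i <- (x + y) / 2
  mu <- mean(m_i)
  msb <- 2 * sum((m_i - mu)^2) / (n - 1)
  msw <- sum((x - m_i)^2 + (y - m_i)^2) / n
  undefined <- (msb + msw) <= 0
  icc <- if (undefined) NA_real_ else (msb - msw) / (msb + msw)
  structure(list(icc = icc, cov = if (mu != 0) sqrt(msw) / mu else NA_real_,
                 mu = mu, sigma_between = msb, sigma_within = msw,
                 undefined = undefined),
            class = "reliability_result")
}

#' Double-entry intraclass correlation of sibling pairs
#'
#' Pearson correlation with every pair entered in both orders, so the
#' result is invariant to within-pair ordering.
#'
#' @param x,y paired sibling values.
#' @return scalar correlation (`NA` when variance is zero).
#' @export
pair_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 pairs")
  a <- c(x, y); b <- c(y, x)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Falconer's broad-sense heritability
#'
#' `H2b = 2 * (r_MZ - r_DZ)`.
#'
#' @param r_mz,r_dz monozygotic and dizygotic twin-pair correlations in
#'   `[-1, 1]`.
#' @return scalar heritability estimate.
#' @export
falconer <- function(r_mz, r_dz) {
  if (any(abs(c(r_mz, r_dz)) > 1)) stop("correlations must lie in [-1, 1]")
  2 * (r_mz - r_dz)
}

#' Extract sibling pairs from a cohort table
#'
#' Siblings are matched on both parental identifiers and split by the
#' zygosity label.  Sibships with more than two members contribute all
#' unordered pairs.
#'
#' @param cohort data frame with columns `subject_id`, `mother_id`,
#'   `father_id`, `zygosity` (labels `"MZ"`, `"DZ"`, `"NT"`, others
#'   ignored).
#' @param value_col column name of the trait value.
#' @return list of data frames (`mz`, `dz`, `nt`) with columns `v1`, `v2`.
#' @export
sibling_pairs <- function(cohort, value_col) {
  out <- list()
  for (zg in c("MZ", "DZ", "NT")) {
    sub <- cohort[cohort$zygosity == zg, , drop = FALSE]
    fam <- split(sub[[value_col]], paste(sub$mother_id, sub$father_id))
    v1 <- c(); v2 <- c()
    for (vals in fam) {
      if (length(vals) < 2L) next
      cmb <- utils::combn(length(vals), 2L)
      v1 <- c(v1, vals[cmb[1L, ]])
      v2 <- c(v2, vals[cmb[2L, ]])
    }
    out[[tolower(zg)]] <- data.frame(v1 = v1, v2 = v2)
  }
  out
}

#' Twin heritability analysis of a cohort metric
#'
#' Computes the double-entry MZ, DZ and NT sibling correlations and the
#' Falconer heritability estimate.
#'
#' @inheritParams sibling_pairs
#' @return list with `r_mz`, `r_dz`, `r_nt`, `h2b`, and pair counts.
#' @export
heritability_analysis <- function(cohort, value_col) {
  p <- sibling_pairs(cohort, value_col)
  r_mz <- pair_correlation(p$mz$v1, p$mz$v2)
  r_dz <- pair_correlation(p$dz$v1, p$dz$v2)
  r_nt <- if (nrow(p$nt) >= 3L) pair_correlation(p$nt$v1, p$nt$v2) else NA_real_
  list(r_mz = r_mz, r_dz = r_dz, r_nt = r_nt,
       h2b = falconer(r_mz, r_dz),
       n_mz = nrow(p$mz), n_dz = nrow(p$dz), n_nt = nrow(p$nt))
}

#' Group comparison t-test
#'
#' Paired Student's t-test for within-subject (e.g. left-right) contrasts,
#' or a two-sample test (Welch by default) for between-group (e.g.
#' male-female) contrasts.
#'
#' @param x numeric values (first group, or first condition when paired).
#' @param y second group/condition values.
#' @param paired logical.
#' @param var_equal passed to [stats::t.test()] for the unpaired case.
#' @return list with `t`, `p`, `df`, `estimate` (mean difference), and
#'   `undefined` flag for zero-variance input.
#' @export
compare_groups <- function(x, y, paired = FALSE, var_equal = FALSE) {
  ok_x <- is.finite(x); ok_y <- is.finite(y)
  if (paired) {
    ok <- ok_x & ok_y
    d <- x[ok] - y[ok]
    if (length(d) < 2L) stop("need at least 2 pairs")
    if (sd(d) == 0) {
      return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                  p = if (mean(d) == 0) 1 else 0,
                  df = length(d) - 1L, estimate = mean(d), undefined = TRUE))
    }
    tt <- t.test(x[ok], y[ok], paired = TRUE)
  } else {
    x <- x[ok_x]; y <- y[ok_y]
    if (length(x) < 2L || length(y) < 2L) stop("need at least 2 per group")
    if (sd(x) == 0 && sd(y) == 0) {
      d <- mean(x) - mean(y)
      return(list(t = if (d == 0) 0 else sign(d) * Inf,
                  p = if (d == 0) 1 else 0,
                  df = length(x) + length(y) - 2L, estimate = d,
                  undefined = TRUE))
    }
    tt <- t.test(x, y, var.equal = var_equal)
  }
  est <- if (paired) unname(tt$estimate) else unname(diff(rev(tt$estimate)))
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       estimate = est, undefined = FALSE)
}

#' Tukey outlier fence filter
#'
#' Keeps values within `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by
#' linear interpolation (type 7).  `NA` values are marked not retained.
#'
#' @param x numeric vector (n >= 4).
#' @return logical retention mask.
#' @export
tukey_filter <- function(x) {
  fin <- is.finite(x)
  if (sum(fin) < 4L) stop("tukey_filter needs at least 4 finite values")
  q <- quantile(x[fin], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  out <- fin & x >= q[1L] - 1.5 * iqr & x <= q[2L] + 1.5 * iqr
  out[!fin] <- FALSE
  out
}

#' Standardized behavioral regression with Tukey exclusion and delta-BIC
#'
#' Ordinary least squares of a standardized outcome on a standardized
#' predictor plus covariates.  All continuous variables are normalized to
#' zero mean and unit variance (computed on the full cohort) so the
#' predictor coefficient is a standardized beta.  Tukey fences (computed on
#' the full cohort per variable, before fitting) exclude outlying rows of
#' the outcome and predictor.  `delta_bic = BIC(model without predictor) -
#' BIC(model with predictor)` with `BIC = n log(RSS/n) + k log(n)`;
#' positive values favor keeping the predictor.
#'
#' @param data data frame.
#' @param outcome,predictor column names.
#' @param covariates character vector of covariate column names.
#' @return object of class `regression_result`: `r2`, `std_beta`, `se`,
#'   `t_value`, `p_value`, `delta_bic`, `n`.
#' @export
regress_behavior <- function(data, outcome, predictor,
                             covariates = character()) {
  vars <- c(outcome, predictor, covariates)
  if (!all(vars %in% names(data)))
    stop("missing columns: ", paste(setdiff(vars, names(data)), collapse = ", "))
  d <- data[, vars, drop = FALSE]
  # standardize continuous variables on the full cohort
  for (v in vars) {
    if (is.numeric(d[[v]]) && length(unique(d[[v]][is.finite(d[[v]])])) > 2L) {
      mu <- mean(d[[v]], na.rm = TRUE); s <- sd(d[[v]], na.rm = TRUE)
      if (is.na(s) || s == 0) stop("constant variable: ", v)
      d[[v]] <- (d[[v]] - mu) / s
    }
  }
  keep <- tukey_filter(d[[outcome]]) & tukey_filter(d[[predictor]])
  d <- d[keep & complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < length(vars) + 2L) stop("too few complete cases after exclusion")
  rhs_cov <- if (length(covariates)) paste(covariates, collapse = " + ") else NULL
  f_full <- stats::as.formula(paste(outcome, "~",
                                    paste(c(predictor, rhs_cov), collapse = " + ")))
  f_red <- stats::as.formula(paste(outcome, "~",
                                   if (is.null(rhs_cov)) "1" else rhs_cov))
  fit <- lm(f_full, data = d)
  if (any(is.na(coef(fit))))
    stop(sprintf("collinear design (condition number %.3g): drop covariates",
                 kappa(stats::model.matrix(fit))))
  red <- lm(f_red, data = d)
  co <- summary(fit)$coefficients
  row <- co[predictor, ]
  bic_of <- function(m) {
    rss <- sum(stats::residuals(m)^2)
    n * log(rss / n) + length(coef(m)) * log(n)
  }
  structure(list(r2 = summary(fit)$r.squared,
                 std_beta = unname(row[1L]), se = unname(row[2L]),
                 t_value = unname(row[3L]), p_value = unname(row[4L]),
                 delta_bic = bic_of(red) - bic_of(fit), n = n),
            class = "regression_result")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure; returns monotone q-values and the rejection mask at
#' level `q`.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `q_values` and `reject`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  qv <- p.adjust(p, method = "BH")
  list(q_values = qv, reject = !is.na(qv) & qv <= q)
}

#' Population probability map of a parcel
#'
#' Fraction of subjects whose parcel includes each vertex.
#'
#' @param masks V x S logical matrix (or list of per-vertex masks) on a
#'   shared topology.
#' @return numeric per-vertex fraction in `[0, 1]`.
#' @export
probability_map <- function(masks) {
  if (is.list(masks) && !is.matrix(masks)) {
    len <- vapply(masks, length, 1L)
    if (length(unique(len)) != 1L) stop("masks disagree in topology")
    masks <- do.call(cbind, masks)
  }
  rowMeans(masks)
}
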