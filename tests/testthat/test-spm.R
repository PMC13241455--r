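test_that("the SPM t-field equals a per-node OLS oracle", {
  set.seed(31)
  co <- draw_covariates(covariate_spec(n_subjects = 40, seed = 31))
  cc <- simulate_curve_cohort(covariate_spec(n_subjects = 40, seed = 31),
                              noise_sd = 6, seed = 31)
  X <- spm_design(co, "chronicity_yr")
  fit <- fit_glm_field(cc$curves, X)
  for (j in c(1, 17, 50, 101)) {
    df <- data.frame(y = cc$curves[, j], X[, -1, drop = FALSE])
    lmf <- lm(y ~ ., data = df)
    t_or <- summary(lmf)$coefficients["chronicity_yr", "t value"]
    expect_lt(abs(fit$t_field[j] - t_or) / abs(t_or), 1e-10)
  }
  expect_identical(fit$df, nrow(co) - ncol(X))
})

test_that("a response orthogonal to the target gives a zero t-field", {
  co <- draw_covariates(covariate_spec(n_subjects = 30, seed = 32))
  set.seed(5032)  # stream distinct from the covariate draw
  X <- spm_design(co, "chronicity_yr")
  # residualize noise against the full design, then add back nuisance
  # structure: target coefficient is exactly zero by construction
  E <- qr.resid(qr(X), matrix(rnorm(30 * 101), 30, 101))
  Y <- X[, -2, drop = FALSE] %*% matrix(rnorm((ncol(X) - 1) * 101),
                                        ncol(X) - 1, 101) + E
  fit <- fit_glm_field(Y, X)
  expect_lt(max(abs(fit$t_field)), 1e-8)
})

test_that("a zero-residual fit is flagged and yields infinite t", {
  co <- draw_covariates(covariate_spec(n_subjects = 25, seed = 33))
  X <- spm_design(co, "chronicity_yr")
  Y <- outer(X[, "chronicity_yr"], rep(1, 101))
  expect_warning(fit <- fit_glm_field(Y, X), "zero residual")
  expect_true(all(is.infinite(fit$t_field)))
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  co <- draw_covariates(covariate_spec(n_subjects = 30, seed = 34))
  co$bmi <- co$age  # identical after z-scoring
  expect_error(spm_design(co, "chronicity_yr"), "collinear.*bmi")
})

test_that("residual smoothness estimation tracks the generating kernel", {
  set.seed(35)
  # white noise: FWHM near the grid spacing
  expect_lt(estimate_fwhm(matrix(rnorm(60 * 101), 60, 101)), 4)
  # monotone in the smoothing kernel width
  est <- sapply(c(5, 10, 20, 40), function(f)
    estimate_fwhm(fatmapr:::smooth_gaussian_curves(60, fwhm = f)))
  expect_true(all(diff(est) > 0))
  expect_true(all(abs(est - c(5, 10, 20, 40)) / c(5, 10, 20, 40) < 0.35))
  # perfectly correlated field: smooth limit
  R1 <- outer(rnorm(20), sin(seq(0, 3, length.out = 101)))
  expect_warning(f1 <- estimate_fwhm(R1), "correlated")
  expect_identical(f1, 100)
})

test_that("the RFT threshold reaches the pointwise quantile in the smooth limit and is monotone", {
  expect_lt(abs(rft_threshold(100, 100, 100, 0.05, 2) - qt(0.975, 100)) /
              qt(0.975, 100), 0.01)
  expect_gt(rft_threshold(50, 5, 100, 0.05, 2),
            rft_threshold(50, 20, 100, 0.05, 2))
  # one-tailed threshold is lower than two-tailed at the same alpha
  expect_lt(rft_threshold(50, 10, 100, 0.05, 1),
            rft_threshold(50, 10, 100, 0.05, 2))
  expect_error(rft_threshold(50, 10, 100, alpha = 0), "alpha")
  expect_error(rft_threshold(50, 10, 100, alpha = 1.2), "alpha")
})

test_that("cluster extraction interpolates threshold crossings analytically", {
  tf <- rep(0, 101)
  tf[41:60] <- 5  # supra-threshold at grid 40..59
  tf[40] <- 1; tf[61] <- 1
  tc <- 3
  cl <- extract_clusters(tf, tc, grid = 0:100)
  expect_identical(nrow(cl), 1L)
  # crossing between grid 39 (t=1) and grid 40 (t=5): 39 + (3-1)/(5-1)
  expect_equal(cl$start_pct, 39 + 2 / 4, tolerance = 1e-12)
  expect_equal(cl$end_pct, 59 + (3 - 5) / (1 - 5), tolerance = 1e-12)
  expect_identical(cl$sign, 1)
  expect_equal(cl$peak_t, 5)
  # below threshold everywhere -> empty
  expect_identical(nrow(extract_clusters(rep(1, 101), tc)), 0L)
  # two disjoint signed runs, ordered by start
  tf2 <- rep(0, 101)
  tf2[10:15] <- 4; tf2[70:80] <- -4
  cl2 <- extract_clusters(tf2, tc)
  expect_identical(nrow(cl2), 2L)
  expect_true(cl2$start_pct[1] < cl2$start_pct[2])
  expect_identical(cl2$sign, c(1, -1))
})

test_that("cluster extents shrink monotonically as the threshold is raised", {
  set.seed(36)
  tf <- as.vector(fatmapr:::smooth_gaussian_curves(1, fwhm = 15, sd = 3))
  ext <- sapply(c(1.5, 2, 2.5, 3), function(tc) {
    cl <- extract_clusters(tf, tc)
    if (nrow(cl) == 0) 0 else sum(cl$extent)
  })
  expect_true(all(diff(ext) <= 0))
})

test_that("the t-field is invariant to affine rescaling of the target covariate", {
  cc <- simulate_curve_cohort(covariate_spec(n_subjects = 60, seed = 37),
                              seed = 37)
  r1 <- spm_test(cc$curves, cc$cohort, "chronicity_yr")
  co2 <- cc$cohort
  co2$chronicity_yr <- co2$chronicity_yr * 12 + 100  # years -> shifted months
  r2 <- spm_test(cc$curves, co2, "chronicity_yr")
  expect_equal(r1$t_field, r2$t_field, tolerance = 1e-9)
  expect_equal(r1$t_crit, r2$t_crit, tolerance = 1e-9)
})

test_that("an injected deep effect is recovered as an overlapping cluster", {
  cc <- simulate_curve_cohort(
    covariate_spec(n_subjects = 223, seed = 38),
    effects = list(effect_spec("chronicity_yr", c(0, 24), 1.5, "L4L5", 1)),
    noise_sd = 4, seed = 38)
  res <- spm_test(cc$curves, cc$cohort, "chronicity_yr")
  expect_gte(best_recovery_jaccard(res$clusters, c(0, 24)), 0.5)
  expect_true(all(res$clusters$start_pct >= 0 & res$clusters$end_pct <= 100))
  expect_true(all(res$clusters$extent > 0))
})

test_that("permuting the target covariate destroys detected clusters", {
  cc <- simulate_curve_cohort(
    covariate_spec(n_subjects = 150, seed = 39),
    effects = list(effect_spec("chronicity_yr", c(0, 24), 1.5, "L4L5", 1)),
    noise_sd = 4, seed = 39)
  set.seed(39)
  n_null <- sum(replicate(30, {
    co <- cc$cohort
    co$chronicity_yr <- sample(co$chronicity_yr)
    nrow(spm_test(cc$curves, co, "chronicity_yr")$clusters) == 0
  }))
  expect_gte(n_null / 30, 0.85)  # ~1 - alpha of permuted cohorts are null
})

test_that("spm_test drops incomplete subjects listwise and warns on tiny cohorts", {
  cc <- simulate_curve_cohort(covariate_spec(n_subjects = 40, seed = 40),
                              seed = 40)
  co <- cc$cohort
  co$bmi[1:3] <- NA
  expect_message(res <- spm_test(cc$curves, co, "chronicity_yr"), "3 subject")
  expect_identical(res$n, 37L)
  expect_identical(res$n_dropped, 3L)
  cc2 <- simulate_curve_cohort(covariate_spec(n_subjects = 12, seed = 41),
                               seed = 41)
  expect_warning(spm_test(cc2$curves, cc2$cohort, "chronicity_yr"),
                 "fewer than 20")
})

test_that("spm reports serialize to machine-readable JSON", {
  cc <- simulate_curve_cohort(
    covariate_spec(n_subjects = 100, seed = 42),
    effects = list(effect_spec("chronicity_yr", c(0, 24), 2, "L4L5", 1)),
    seed = 42)
  res <- spm_test(cc$curves, cc$cohort, "chronicity_yr")
  tf <- tempfile(fileext = ".json")
  spm_report(res, tf)
  rep <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_identical(rep$target, "chronicity_yr")
  expect_identical(rep$level, "L4L5")
  expect_equal(rep$t_crit, res$t_crit, tolerance = 1e-12)
  expect_identical(nrow(rep$clusters), nrow(res$clusters))
  unlink(tf)
})
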