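# A subject-summary table with a deep15 metric drawn independently of the
# covariates, onto which tests graft known linear structure.
make_summary_tab <- function(n, seed) {
  co <- draw_covariates(covariate_spec(n_subjects = n, seed = seed))
  set.seed(seed + 5000)  # stream distinct from the covariate draw
  data.frame(id = co$id,
             deep15_mean = rnorm(n, 45, 8),
             overall_mean = rnorm(n, 25, 6),
             ddd_mean = (co$pfirrmann_L4L5 + co$pfirrmann_L5S1) / 2,
             age = co$age, sex = co$sex, bmi = co$bmi,
             pain_nrs = co$pain_nrs, met_min_wk = co$met_min_wk,
             chronicity_yr = co$chronicity_yr,
             stringsAsFactors = FALSE)
}

test_that("a noise-free linear construction is fit exactly", {
  tab <- make_summary_tab(80, 51)
  b <- c(-16, 0.17, 2.04, 0.14, -0.9, 0.18)
  tab$chronicity_yr <- b[1] + b[2] * tab$deep15_mean + b[3] * tab$ddd_mean +
    b[4] * tab$age + b[5] * (tab$sex == "F") + b[6] * tab$bmi
  fit <- suppressWarnings(chronicity_regression(tab, "deep15"))  # interpolating fit
  expect_identical(nrow(fit$coef), 6L)
  expect_equal(fit$coef$estimate, b, tolerance = 1e-8)
})

test_that("generating coefficients are recovered within 2 SE", {
  tab <- make_summary_tab(223, 52)
  b_fi <- 0.17
  set.seed(252)  # stream distinct from the covariate draw
  tab$chronicity_yr <- -16 + b_fi * tab$deep15_mean + 2 * tab$ddd_mean +
    0.14 * tab$age + rnorm(223, 0, 10)
  fit <- chronicity_regression(tab, "deep15")
  row <- fit$coef[fit$coef$term == "deep15_mean", ]
  expect_lt(abs(row$estimate - b_fi), 2 * row$se)
  # activity model: injected MET-age slope
  set.seed(152)
  tab$met_min_wk <- 2000 + 25 * tab$age + rnorm(223, 0, 2500)
  fit3 <- activity_regression(tab)
  row3 <- fit3$coef[fit3$coef$term == "age", ]
  expect_lt(abs(row3$estimate - 25), 2 * row3$se)
})

test_that("permuted outcomes give uniform target p-values", {
  tab0 <- make_summary_tab(150, 53)
  set.seed(53)
  ps <- replicate(100, {
    tab0$chronicity_yr <- sample(tab0$chronicity_yr)
    fit <- chronicity_regression(tab0, "deep15")
    fit$coef$p[fit$coef$term == "deep15_mean"]
  })
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})

test_that("independent activity yields mostly null slopes in the activity model", {
  set.seed(54)
  allnull <- replicate(20, {
    tab <- make_summary_tab(223, sample.int(2^30, 1))
    fit <- activity_regression(tab)  # MET independent of all predictors
    all(fit$coef$p[fit$coef$term != "(Intercept)"] > 0.05)
  })
  expect_gte(mean(allnull), 0.5)
})

test_that("degenerate model inputs are rejected", {
  tab <- make_summary_tab(50, 55)
  tab$met_min_wk <- 0
  expect_error(activity_regression(tab), "constant outcome")
  tab2 <- make_summary_tab(50, 56)
  tab2$deep15_mean <- 45
  expect_error(chronicity_regression(tab2, "deep15"), "constant predictor")
})

# Long table with known mixed-model structure on the standardized scale.
make_long_tab <- function(n, seed, b, sd_id = 8, sd_eps = 5) {
  co <- draw_covariates(covariate_spec(n_subjects = n, seed = seed))
  set.seed(seed + 5000)  # stream distinct from the covariate draw
  long <- data.frame(
    id = rep(co$id, each = 2),
    level = factor(rep(c("L4L5", "L5S1"), n), levels = c("L4L5", "L5S1")),
    chronicity_yr = rep(co$chronicity_yr, each = 2),
    met_min_wk = rep(co$met_min_wk, each = 2),
    pain_nrs = rep(co$pain_nrs, each = 2),
    age = rep(co$age, each = 2), sex = rep(co$sex, each = 2),
    bmi = rep(co$bmi, each = 2), stringsAsFactors = FALSE)
  long$ddd <- ifelse(long$level == "L4L5", rep(co$pfirrmann_L4L5, each = 2),
                     rep(co$pfirrmann_L5S1, each = 2))
  zs <- function(x) (x - mean(x)) / sd(x)
  long$deep15_fi <- b[1] + b[2] * zs(long$chronicity_yr) + b[3] * zs(long$ddd) +
    b[4] * zs(long$met_min_wk) + b[5] * zs(long$pain_nrs) + b[6] * zs(long$age) +
    b[7] * (long$sex == "F") + b[8] * zs(long$bmi) +
    b[9] * (long$level == "L5S1") +
    rep(rnorm(n, 0, sd_id), each = 2) + rnorm(2 * n, 0, sd_eps)
  long$overall_fi <- long$deep15_fi
  long
}

b_true <- c(46, 2.33, 2.12, -1.75, 1.61, 3.13, 6.62, 0.55, 11.45)

test_that("the mixed model recovers an injected level offset within 2 SE", {
  long <- make_long_tab(223, 57, b_true)
  fit <- mixed_fi_model(long, "deep15")
  expect_true(fit$converged)
  expect_identical(fit$n_obs, 446L)
  expect_identical(fit$n_subjects, 223L)
  row <- fit$coef[fit$coef$term == "levelL5S1", ]
  expect_lt(abs(row$estimate - 11.45), 2 * row$se)
  expect_true(all(fit$coef$se > 0))
})

test_that("zero between-subject variance gives a near-zero random intercept", {
  long <- make_long_tab(120, 58, b_true, sd_id = 0, sd_eps = 5)
  fit <- suppressMessages(mixed_fi_model(long, "deep15"))
  expect_lt(fit$ranef_sd, 1)
})

test_that("mixed fixed effects match an OLS cluster-robust oracle on balanced data", {
  long <- make_long_tab(200, 59, b_true)
  # raw scales (MET in thousands) trigger lme4's rescaling advice; harmless here
  fit <- suppressWarnings(mixed_fi_model(long, "deep15", standardize = FALSE))
  ols <- lm(deep15_fi ~ chronicity_yr + ddd + met_min_wk + pain_nrs + age +
              sex + bmi + level, data = long)
  # balanced two-row-per-subject design: GLS and OLS point estimates agree
  # closely for subject-constant covariates
  keep <- c("(Intercept)", "chronicity_yr", "met_min_wk", "pain_nrs",
            "age", "sexF", "bmi", "levelL5S1")
  expect_equal(fit$coef$estimate[match(keep, fit$coef$term)],
               unname(coef(ols)[keep]), tolerance = 0.05)
  # and the mixed-model SEs track cluster-robust sandwich SEs
  vc <- sandwich::vcovCL(ols, cluster = long$id)
  se_rob <- sqrt(diag(vc))[keep]
  se_lmm <- fit$coef$se[match(keep, fit$coef$term)]
  expect_true(all(abs(se_lmm / se_rob - 1) < 0.2))
})

test_that("deep15 and overall mixed models differ only in the outcome column", {
  long <- make_long_tab(100, 60, b_true)
  set.seed(60)
  long$overall_fi <- long$deep15_fi + rnorm(nrow(long), 0, 1)
  f1 <- mixed_fi_model(long, "deep15")
  f2 <- mixed_fi_model(long, "overall")
  expect_identical(f1$coef$term, f2$coef$term)
  expect_false(isTRUE(all.equal(f1$coef$estimate, f2$coef$estimate)))
  # same input table, same n
  expect_identical(f1$n_obs, f2$n_obs)
})

test_that("metric and long tables assemble and log listwise deletion", {
  sim <- simulate_cohort(covariate_spec(n_subjects = 4, seed = 61),
                         noise_sd = 2, seed = 61)
  ext <- extract_cohort_curves(sim$subjects)
  co <- sim$cohort
  co$bmi[1] <- NA
  tab <- subject_summary_table(ext$metrics, co)
  expect_identical(attr(tab, "n_dropped"), 1L)
  expect_true(all(c("deep15_mean", "overall_mean", "ddd_mean") %in% names(tab)))
  long <- level_long_table(ext$metrics, co)
  expect_identical(attr(long, "n_dropped"), 2L)  # both levels of the NA subject
  expect_identical(nrow(long), 6L)
  expect_true(all(long$ddd[long$level == "L4L5"] ==
                    co$pfirrmann_L4L5[match(long$id[long$level == "L4L5"], co$id)]))
})
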