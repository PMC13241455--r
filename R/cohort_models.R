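# Scalar-outcome stage: multivariable regressions of chronicity and of
# physical activity, and linear mixed-effects models of the per-level FI
# metrics across the two lumbar levels with a per-subject random intercept.

new_model_fit <- function(formula_str, coef, n_obs, n_subjects,
                          converged = TRUE, extra = list()) {
  structure(c(list(formula = formula_str, coef = coef, n_obs = n_obs,
                   n_subjects = n_subjects, converged = converged), extra),
            class = "model_fit")
}

#' @method print model_fit
#' @export
print.model_fit <- function(x, ...) {
  cat(x$formula, "\n")
  cat(sprintf("n_obs = %d, n_subjects = %d, converged = %s\n",
              x$n_obs, x$n_subjects, x$converged))
  print(format(x$coef, digits = 3), row.names = FALSE)
  invisible(x)
}

lm_coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             df = stats::df.residual(fit), p = sm[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}

check_nonconstant <- function(df, cols, what = "predictor") {
  for (cl in cols) {
    x <- df[[cl]]
    if (is.numeric(x) && stats::sd(x) == 0)
      stop("constant ", what, ": '", cl, "'")
  }
}

#' Per-subject summary table joining FI metrics to covariates
#'
#' Averages the two lumbar levels' metrics into per-subject means
#' (`deep15_mean`, `overall_mean`) and the mean Pfirrmann disc-degeneration
#' grade (`ddd_mean`), joined to the cohort covariates; complete cases
#' only, with the number of dropped subjects recorded in attribute
#' `n_dropped`.
#'
#' @param metrics data.frame (subject, level, overall_fi, deep15_fi).
#' @param cohort cohort covariate table.
#' @return one-row-per-subject data.frame.
#' @export
subject_summary_table <- function(metrics, cohort) {
  ag <- stats::aggregate(cbind(deep15_fi, overall_fi) ~ subject,
                         data = metrics, FUN = mean)
  names(ag) <- c("id", "deep15_mean", "overall_mean")
  co <- cohort
  co$ddd_mean <- (co$pfirrmann_L4L5 + co$pfirrmann_L5S1) / 2
  tab <- merge(ag, co, by = "id")
  cc <- stats::complete.cases(tab)
  out <- tab[cc, , drop = FALSE]
  attr(out, "n_dropped") <- nrow(cohort) - nrow(out)
  out
}

#' Two-rows-per-subject table for the mixed-effects models
#'
#' One row per subject x lumbar level, with the level-specific FI metrics
#' and the level-specific Pfirrmann grade (`ddd`), joined to the subject's
#' covariates.
#'
#' @inheritParams subject_summary_table
#' @return long data.frame with columns `id`, `level`, `deep15_fi`,
#'   `overall_fi`, `ddd`, and the covariates.
#' @export
level_long_table <- function(metrics, cohort) {
  m <- metrics
  names(m)[names(m) == "subject"] <- "id"
  tab <- merge(m, cohort, by = "id")
  tab$ddd <- ifelse(tab$level == "L4L5", tab$pfirrmann_L4L5,
                    tab$pfirrmann_L5S1)
  tab$level <- factor(tab$level, levels = c("L4L5", "L5S1"))
  cc <- stats::complete.cases(tab)
  out <- tab[cc, , drop = FALSE]
  attr(out, "n_dropped") <- nrow(tab) - nrow(out)
  out[order(out$id, out$level), , drop = FALSE]
}

#' Multivariable regression of cLBP chronicity on muscle and disc state
#'
#' OLS of chronicity (years) on a per-subject mean FI metric (deep15 or
#' overall), mean disc degeneration grade, age, sex (reference male) and
#' BMI — six terms including the intercept.
#'
#' @param tab table from [subject_summary_table()].
#' @param metric `"deep15"` or `"overall"`: which mean FI metric enters.
#' @return a `model_fit`.
#' @export
chronicity_regression <- function(tab, metric = c("deep15", "overall")) {
  metric <- match.arg(metric)
  fi_col <- paste0(metric, "_mean")
  check_nonconstant(tab, c(fi_col, "ddd_mean", "age", "bmi"))
  fml <- stats::reformulate(c(fi_col, "ddd_mean", "age", "sex", "bmi"),
                            response = "chronicity_yr")
  fit <- stats::lm(fml, data = tab)
  new_model_fit(
    sprintf("chronicity_yr ~ %s + ddd_mean + age + sex + bmi", fi_col),
    lm_coef_table(fit), n_obs = as.integer(stats::nobs(fit)),
    n_subjects = as.integer(stats::nobs(fit)),
    extra = list(lm = fit))
}

#' Multivariable regression of weekly physical activity
#'
#' OLS of MET-min/wk on chronicity, pain severity, age, sex and BMI.
#'
#' @param tab table from [subject_summary_table()] (or any table with the
#'   required columns).
#' @return a `model_fit`.
#' @export
activity_regression <- function(tab) {
  if (stats::sd(tab$met_min_wk) == 0) stop("constant outcome: 'met_min_wk'")
  check_nonconstant(tab, c("chronicity_yr", "pain_nrs", "age", "bmi"))
  fit <- stats::lm(met_min_wk ~ chronicity_yr + pain_nrs + age + sex + bmi,
                   data = tab)
  new_model_fit(
    "met_min_wk ~ chronicity_yr + pain_nrs + age + sex + bmi",
    lm_coef_table(fit), n_obs = as.integer(stats::nobs(fit)),
    n_subjects = as.integer(stats::nobs(fit)),
    extra = list(lm = fit))
}

#' Linear mixed-effects model of per-level FI across lumbar levels
#'
#' REML fit of the level-specific FI metric on chronicity, level-specific
#' disc degeneration, physical activity, pain intensity, age, sex, BMI and
#' lumbar level, with a random intercept per subject (two rows per
#' subject). Continuous fixed effects are z-scored by default, so
#' estimates are FI% per SD of the predictor; p-values use
#' Satterthwaite-approximated degrees of freedom. Non-convergence under
#' REML is flagged and triggers a maximum-likelihood refit.
#'
#' @param long table from [level_long_table()].
#' @param outcome `"deep15"` or `"overall"`.
#' @param standardize z-score continuous fixed effects (default TRUE).
#' @return a `model_fit` with extra fields `ranef_sd` (between-subject SD)
#'   and `sigma` (residual SD).
#' @export
mixed_fi_model <- function(long, outcome = c("deep15", "overall"),
                           standardize = TRUE) {
  outcome <- match.arg(outcome)
  ycol <- paste0(outcome, "_fi")
  d <- long
  cont <- c("chronicity_yr", "ddd", "met_min_wk", "pain_nrs", "age", "bmi")
  if (standardize) {
    for (cl in cont) {
      s <- stats::sd(d[[cl]])
      d[[cl]] <- if (s == 0) d[[cl]] - mean(d[[cl]]) else
        (d[[cl]] - mean(d[[cl]])) / s
    }
  }
  fml <- stats::as.formula(paste(
    ycol, "~ chronicity_yr + ddd + met_min_wk + pain_nrs + age + sex +",
    "bmi + level + (1 | id)"))
  fit <- lmerTest::lmer(fml, data = d, REML = TRUE)
  # a singular (zero-variance random intercept) fit is a legitimate
  # boundary estimate, not a convergence failure
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  conv <- length(msgs[!grepl("singular", msgs)]) == 0L
  if (!conv) {
    message("REML fit did not converge cleanly; refitting with ML")
    fit <- lmerTest::lmer(fml, data = d, REML = FALSE)
  }
  sm <- summary(fit)$coefficients  # estimate, SE, df (Satterthwaite), t, p
  coef <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                     se = sm[, "Std. Error"], df = sm[, "df"],
                     p = sm[, "Pr(>|t|)"], row.names = NULL,
                     stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  new_model_fit(
    paste0(ycol, " ~ chronicity + ddd + activity + pain + age + sex + bmi",
           " + level + (1|id)"),
    coef, n_obs = as.integer(stats::nobs(fit)),
    n_subjects = as.integer(lme4::ngrps(fit)[["id"]]),
    converged = conv,
    extra = list(lmer = fit,
                 ranef_sd = vc$sdcor[vc$grp == "id"],
                 sigma = vc$sdcor[vc$grp == "Residual"],
                 standardized = standardize))
}
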