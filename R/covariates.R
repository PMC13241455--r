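#' Specification of the synthetic cohort's covariate distributions
#'
#' Defaults reproduce the marginal distributions of a chronic low back pain
#' (cLBP) imaging cohort of 223 adults (103 male, 120 female): pooled age
#' 53.0 +/- 15.4 yr, BMI 26.1 +/- 4.4 kg/m^2, pain intensity 4.45 +/- 1.9 on
#' the 0-10 numeric rating scale, cLBP chronicity 11.9 +/- 12.7 yr, and
#' weekly physical activity 3164.8 +/- 2920.4 MET-min/wk. Chronicity is
#' left-truncated at 0.25 yr (pain for at least three of the past six
#' months) and MET-minutes at 0; for both, the underlying normal location is
#' calibrated at draw time so the *truncated* mean matches the requested
#' mean. Pain draws are clipped to [0, 10].
#'
#' @param n_subjects number of subjects to draw.
#' @param age_mean_sd,bmi_mean_sd,chronicity_mean_sd,met_mean_sd,pain_mean_sd
#'   length-2 numeric vectors `c(mean, sd)`; units: years, kg/m^2, years,
#'   MET-min/wk, NRS points.
#' @param sex_fraction_female probability a subject is female.
#' @param pfirrmann_probs probability vector over disc-degeneration grades
#'   1-5, used independently at each lumbar level.
#' @param cor_matrix optional correlation matrix (Gaussian copula) over the
#'   five continuous covariates in the order age, bmi, pain, chronicity,
#'   met; default identity (independent draws).
#' @param seed integer seed making the draw reproducible.
#' @return an object of class `covariate_spec`.
#' @export
covariate_spec <- function(n_subjects = 223L,
                           age_mean_sd = c(53.0, 15.4),
                           bmi_mean_sd = c(26.1, 4.4),
                           pain_mean_sd = c(4.45, 1.9),
                           chronicity_mean_sd = c(11.9, 12.7),
                           met_mean_sd = c(3164.8, 2920.4),
                           sex_fraction_female = 120 / 223,
                           pfirrmann_probs = c(0.05, 0.20, 0.35, 0.28, 0.12),
                           cor_matrix = NULL,
                           seed = 1L) {
  spec <- list(
    n_subjects = as.integer(n_subjects),
    age_mean_sd = as.numeric(age_mean_sd),
    bmi_mean_sd = as.numeric(bmi_mean_sd),
    pain_mean_sd = as.numeric(pain_mean_sd),
    chronicity_mean_sd = as.numeric(chronicity_mean_sd),
    met_mean_sd = as.numeric(met_mean_sd),
    sex_fraction_female = as.numeric(sex_fraction_female),
    pfirrmann_probs = as.numeric(pfirrmann_probs),
    cor_matrix = cor_matrix,
    seed = as.integer(seed)
  )
  class(spec) <- "covariate_spec"
  validate_covariate_spec(spec)
  spec
}

validate_covariate_spec <- function(spec) {
  pairs <- spec[c("age_mean_sd", "bmi_mean_sd", "pain_mean_sd",
                  "chronicity_mean_sd", "met_mean_sd")]
  for (nm in names(pairs)) {
    v <- pairs[[nm]]
    if (length(v) != 2L || any(!is.finite(v)))
      stop(sprintf("%s must be a finite (mean, sd) pair", nm))
    if (v[2] < 0) stop(sprintf("%s: sd must be >= 0", nm))
  }
  if (spec$n_subjects < 1L) stop("n_subjects must be >= 1")
  if (!is.finite(spec$sex_fraction_female) ||
      spec$sex_fraction_female < 0 || spec$sex_fraction_female > 1)
    stop("sex_fraction_female must lie in [0, 1]")
  p <- spec$pfirrmann_probs
  if (length(p) != 5L || any(!is.finite(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-9)
    stop("pfirrmann_probs must be 5 nonnegative values summing to 1")
  if (!is.null(spec$cor_matrix)) {
    cm <- spec$cor_matrix
    if (!is.matrix(cm) || any(dim(cm) != 5L) || any(abs(cm - t(cm)) > 1e-12))
      stop("cor_matrix must be a symmetric 5x5 matrix")
    if (min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("cor_matrix must be positive semi-definite")
  }
  invisible(spec)
}

#' Draw a table of subject records from a covariate specification
#'
#' Continuous covariates are drawn through a Gaussian copula (identity
#' correlation by default, i.e. independent), with truncated-normal margins
#' for chronicity (>= 0.25 yr) and MET-minutes (>= 0) whose location is
#' calibrated so the truncated mean equals the specified mean. Sex is
#' Bernoulli(`sex_fraction_female`); per-level Pfirrmann grades are
#' independent categorical draws over grades 1-5.
#'
#' @param spec a [covariate_spec()].
#' @return a data.frame with one row per subject and columns `id`, `age`,
#'   `sex` (factor, levels M/F, reference M), `bmi`, `pain_nrs`,
#'   `chronicity_yr`, `met_min_wk`, `pfirrmann_L4L5`, `pfirrmann_L5S1`.
#' @export
draw_covariates <- function(spec) {
  validate_covariate_spec(spec)
  n <- spec$n_subjects
  with_seed(spec$seed, {
    z <- matrix(stats::rnorm(n * 5L), n, 5L)
    if (!is.null(spec$cor_matrix)) {
      ev <- eigen(spec$cor_matrix, symmetric = TRUE)
      L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
      z <- z %*% L
    }
    age <- spec$age_mean_sd[1] + spec$age_mean_sd[2] * z[, 1]
    bmi <- spec$bmi_mean_sd[1] + spec$bmi_mean_sd[2] * z[, 2]
    pain <- pmin(10, pmax(0, spec$pain_mean_sd[1] + spec$pain_mean_sd[2] * z[, 3]))
    chron <- rtrunc_norm(
      z[, 4],
      mean = calibrate_trunc_mu(spec$chronicity_mean_sd[1],
                                spec$chronicity_mean_sd[2], 0.25),
      sd = spec$chronicity_mean_sd[2], lower = 0.25)
    met <- rtrunc_norm(
      z[, 5],
      mean = calibrate_trunc_mu(spec$met_mean_sd[1], spec$met_mean_sd[2], 0),
      sd = spec$met_mean_sd[2], lower = 0)
    sex <- factor(ifelse(stats::runif(n) < spec$sex_fraction_female, "F", "M"),
                  levels = c("M", "F"))
    pf1 <- sample.int(5L, n, replace = TRUE, prob = spec$pfirrmann_probs)
    pf2 <- sample.int(5L, n, replace = TRUE, prob = spec$pfirrmann_probs)
    data.frame(
      id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex, bmi = bmi, pain_nrs = pain,
      chronicity_yr = chron, met_min_wk = met,
      pfirrmann_L4L5 = pf1, pfirrmann_L5S1 = pf2,
      stringsAsFactors = FALSE
    )
  })
}

#' Weekly MET-minutes from IPAQ activity items
#'
#' Standard International Physical Activity Questionnaire (short form)
#' scoring: MET-min/wk = 8.0 x vigorous days x min/day +
#' 4.0 x moderate days x min/day + 3.3 x walking days x min/day.
#'
#' @param vigorous_days,vigorous_min days/wk and min/day of vigorous activity.
#' @param moderate_days,moderate_min days/wk and min/day of moderate activity.
#' @param walking_days,walking_min days/wk and min/day of walking.
#' @return weekly MET-minutes (numeric, vectorized).
#' @export
met_minutes_from_ipaq <- function(vigorous_days = 0, vigorous_min = 0,
                                  moderate_days = 0, moderate_min = 0,
                                  walking_days = 0, walking_min = 0) {
  args <- list(vigorous_days, vigorous_min, moderate_days, moderate_min,
               walking_days, walking_min)
  if (any(vapply(args, function(a) any(!is.finite(a) | a < 0), logical(1))))
    stop("IPAQ inputs must be finite and nonnegative")
  mins <- list(vigorous_min, moderate_min, walking_min)
  if (any(vapply(mins, function(m) any(m > 1440), logical(1))))
    stop("minutes per day cannot exceed 1440")
  8.0 * vigorous_days * vigorous_min +
    4.0 * moderate_days * moderate_min +
    3.3 * walking_days * walking_min
}
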