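# One-dimensional statistical parametric mapping (SPM) for radial fat
# curves: a general linear model is fitted at every node of the 101-node
# depth grid, the t-statistic field for one covariate is thresholded via
# random field theory (RFT) at familywise alpha, and supra-threshold
# clusters are reported with interpolated endpoints.

#' Build an SPM design matrix from a cohort table
#'
#' Intercept + covariate of interest + adjusters. Continuous columns are
#' z-scored (which leaves the t-field unchanged but conditions the solve);
#' `sex` enters as a female indicator (reference male).
#'
#' @param cohort cohort data.frame (columns as in [draw_covariates()]).
#' @param target name of the covariate of interest.
#' @param adjusters character vector of adjuster columns
#'   (default `c("age", "sex", "bmi")`).
#' @param standardize z-score continuous columns (default TRUE).
#' @return numeric matrix with named columns; attribute `target` gives the
#'   target column name.
#' @export
spm_design <- function(cohort, target, adjusters = c("age", "sex", "bmi"),
                       standardize = TRUE) {
  enc <- function(col) {
    x <- cohort[[col]]
    if (is.null(x)) stop("cohort has no column '", col, "'")
    if (col == "sex" || is.factor(x) || is.character(x)) {
      as.numeric(factor(x, levels = c("M", "F")) == "F")
    } else if (standardize) {
      s <- stats::sd(x)
      if (s == 0) x - mean(x) else (x - mean(x)) / s
    } else x
  }
  cols <- c(target, setdiff(adjusters, target))
  X <- cbind(intercept = 1, sapply(cols, enc))
  colnames(X) <- c("intercept", cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  attr(X, "target") <- target
  X
}

#' Fit the node-wise general linear model and form the SPM t-field
#'
#' Ordinary least squares of the curve matrix on the design at every grid
#' node; t = beta_target / SE(beta_target) with residual degrees of freedom
#' nu = n - p. Residual curves are retained for smoothness estimation.
#'
#' @param Y n x m matrix of curves (subjects x nodes), no missing values.
#' @param X design matrix from [spm_design()] (full column rank).
#' @param target target column name (default the design's `target`
#'   attribute).
#' @return list with `t_field` (length m), `beta` (p x m), `residuals`
#'   (n x m), `df`, `se`.
#' @export
fit_glm_field <- function(Y, X, target = attr(X, "target")) {
  stopifnot(is.matrix(Y), nrow(Y) == nrow(X))
  if (any(!is.finite(Y))) stop("curve matrix contains missing or non-finite nodes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  n <- nrow(X); p <- ncol(X); nu <- n - p
  if (nu < 1L) stop("need more subjects than design columns")
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / nu
  # numerically zero residual variance (interpolating fit) -> degenerate t
  zero <- sigma2 <= 1e-20 * (colMeans(Y^2) + 1)
  XtXinv <- chol2inv(qr.R(qrX))
  j <- match(target, colnames(X))
  if (is.na(j)) stop("target column '", target, "' not in design")
  se <- sqrt(sigma2 * XtXinv[j, j])
  tf <- beta[j, ] / se
  if (any(zero)) {
    warning("zero residual variance at some nodes; t set to +/-Inf there")
    tf[zero] <- sign(beta[j, zero]) * Inf
  }
  list(t_field = unname(tf), beta = beta, residuals = res,
       df = nu, se = unname(se))
}

#' Estimate field smoothness (FWHM) from GLM residuals
#'
#' Lattice-based estimator from the random-field literature: each node of
#' the residual field is normalized to unit sum of squares across curves,
#' the per-node resel density is `sqrt(v / (4 log 2))` where `v` is the
#' squared gradient of the normalized field (central differences), and
#' FWHM is the reciprocal of the mean resel density, in grid-spacing
#' units. Clipped to `[grid spacing, field length]`; a perfectly
#' correlated (rank-1) residual field has zero normalized gradient and
#' returns the field length.
#'
#' @param R n x m residual matrix (n >= 2 curves).
#' @return scalar FWHM in grid units (here, percent of radial width).
#' @export
estimate_fwhm <- function(R) {
  stopifnot(is.matrix(R), nrow(R) >= 2L)
  m <- ncol(R)
  field_len <- as.numeric(m - 1)
  ssq <- colSums(R^2)
  B <- sweep(R, 2, sqrt(ssq + .Machine$double.eps), "/")
  # central differences interior, one-sided at the ends
  G <- matrix(0, nrow(B), m)
  G[, 1] <- B[, 2] - B[, 1]
  G[, m] <- B[, m] - B[, m - 1]
  if (m > 2L) G[, 2:(m - 1)] <- (B[, 3:m] - B[, 1:(m - 2)]) / 2
  v <- colSums(G^2)
  v <- v[is.finite(v) & ssq > 0]
  if (length(v) == 0L || all(v < .Machine$double.eps)) {
    warning("constant/perfectly correlated residual field; FWHM = field length")
    return(field_len)
  }
  rpn <- sqrt(v / (4 * log(2)))
  fwhm <- 1 / mean(rpn)
  if (fwhm >= field_len) {
    warning("residual field effectively perfectly correlated; FWHM clipped to field length")
    return(field_len)
  }
  max(fwhm, 1)
}

# Euler-characteristic density of a 1D t-field (per unit resel).
ec1_t <- function(t, nu) {
  sqrt(4 * log(2)) / (2 * pi) * (1 + t^2 / nu)^(-(nu - 1) / 2)
}

#' Random-field-theory critical threshold for a 1D t-field
#'
#' Smallest t at which the expected Euler characteristic of the
#' supra-threshold set equals the per-tail alpha:
#' `E[EC](t) = P(T > t) + resels * EC1(t)`, with
#' `resels = max(field_length - fwhm, 0) / fwhm`. Counting resels net of
#' the one correlation length already covered by the point term makes the
#' threshold decrease monotonically with smoothness and reach the
#' pointwise t quantile exactly when the field is as smooth as its whole
#' length; for rough fields (`field_length >> fwhm`) it coincides with the
#' usual `field_length / fwhm` count.
#'
#' @param nu residual degrees of freedom (>= 3).
#' @param fwhm field smoothness in grid units.
#' @param field_length field extent in grid units (default 100).
#' @param alpha familywise error level in (0, 1).
#' @param tails 1 or 2; two-tailed uses alpha/2 per tail.
#' @return critical threshold t_crit (> 0).
#' @export
rft_threshold <- function(nu, fwhm, field_length = 100, alpha = 0.05,
                          tails = 2) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  stopifnot(nu >= 3, fwhm > 0, field_length > 0, tails %in% c(1, 2))
  a <- alpha / tails
  resels <- max(field_length - fwhm, 0) / fwhm
  f <- function(t) stats::pt(t, nu, lower.tail = FALSE) + resels * ec1_t(t, nu) - a
  stats::uniroot(f, lower = stats::qt(1 - a, nu), upper = 100,
                 extendInt = "downX", tol = 1e-10)$root
}

# Expected number of supra-threshold clusters and RFT cluster-extent
# p-value (Friston-style approximation for a 1D field).
cluster_p_value <- function(extent, t_crit, nu, fwhm, field_length, resels) {
  Em <- max(resels * ec1_t(t_crit, nu), 1e-12)
  EN <- (field_length / fwhm) * stats::pt(t_crit, nu, lower.tail = FALSE)
  En <- max(EN / Em, 1e-12)            # expected cluster extent, resel units
  beta <- pi / (4 * En^2)              # so that E[extent] matches under exp(-beta k^2)
  k <- extent / fwhm
  p_ext <- exp(-beta * k^2)
  1 - exp(-Em * p_ext)
}

#' Extract signed supra-threshold clusters from a t-field
#'
#' Maximal runs of grid nodes with `|t| > t_crit` and uniform sign; cluster
#' endpoints are refined by linear interpolation of the piecewise-linear
#' t-field to the exact threshold crossing, so extents such as 85-94.6%
#' are expressible. Each cluster carries an RFT extent-based p-value.
#'
#' @param t_field numeric vector of t-values (finite).
#' @param t_crit critical threshold (> 0).
#' @param grid node positions (default `0:100`).
#' @param nu,fwhm degrees of freedom and smoothness used for cluster
#'   p-values (optional; p is NA without them).
#' @return data.frame with columns `start_pct`, `end_pct`, `sign`,
#'   `peak_t`, `extent`, `p`, ordered by `start_pct`.
#' @export
extract_clusters <- function(t_field, t_crit, grid = seq_along(t_field) - 1,
                             nu = NULL, fwhm = NULL) {
  stopifnot(all(is.finite(t_field)), t_crit > 0)
  m <- length(t_field)
  supra <- abs(t_field) > t_crit
  sgn <- sign(t_field)
  out <- list()
  i <- 1L
  while (i <= m) {
    if (!supra[i]) { i <- i + 1L; next }
    s <- sgn[i]
    j <- i
    while (j < m && supra[j + 1L] && sgn[j + 1L] == s) j <- j + 1L
    thr <- s * t_crit
    # interpolated start
    if (i == 1L) start <- grid[1] else {
      t0 <- t_field[i - 1L]; t1 <- t_field[i]
      start <- grid[i - 1L] + (thr - t0) / (t1 - t0) * (grid[i] - grid[i - 1L])
    }
    if (j == m) end <- grid[m] else {
      t0 <- t_field[j]; t1 <- t_field[j + 1L]
      end <- grid[j] + (thr - t0) / (t1 - t0) * (grid[j + 1L] - grid[j])
    }
    pk <- t_field[i:j][which.max(abs(t_field[i:j]))]
    out[[length(out) + 1L]] <- data.frame(
      start_pct = start, end_pct = end, sign = s, peak_t = pk,
      extent = end - start, p = NA_real_)
    i <- j + 1L
  }
  if (length(out) == 0L)
    return(data.frame(start_pct = numeric(0), end_pct = numeric(0),
                      sign = numeric(0), peak_t = numeric(0),
                      extent = numeric(0), p = numeric(0)))
  cl <- do.call(rbind, out)
  cl <- cl[order(cl$start_pct), , drop = FALSE]
  rownames(cl) <- NULL
  if (!is.null(nu) && !is.null(fwhm)) {
    L <- grid[m] - grid[1]
    resels <- max(L - fwhm, 0) / fwhm
    cl$p <- vapply(cl$extent, cluster_p_value, numeric(1),
                   t_crit = t_crit, nu = nu, fwhm = fwhm,
                   field_length = L, resels = resels)
  }
  cl
}

#' SPM analysis of radial fat curves against one covariate
#'
#' Composes design construction, node-wise GLM fitting, residual smoothness
#' estimation, RFT thresholding, and cluster extraction: the full
#' curve-level inference for one covariate of interest at one lumbar
#' level, adjusting for the given covariates.
#'
#' @param curves either an n x 101 matrix (rownames = subject ids) or a
#'   long data.frame (subject, level, node_pct, fi) as written by
#'   [extract_cohort_curves()].
#' @param cohort cohort covariate table.
#' @param target covariate of interest (e.g. `"chronicity_yr"`).
#' @param adjusters adjuster columns (default age, sex, bmi).
#' @param level lumbar level to analyse (used to filter long-format
#'   curves).
#' @param alpha familywise error level.
#' @param tails 1 or 2 (default two-tailed, alpha/2 per tail).
#' @return object of class `spm_result`: `t_field`, `df`, `fwhm`,
#'   `resels`, `t_crit`, `clusters`, `alpha`, `tails`, `target`, `level`,
#'   `n`, `n_dropped`.
#' @export
spm_test <- function(curves, cohort, target, adjusters = c("age", "sex", "bmi"),
                     level = "L4L5", alpha = 0.05, tails = 2) {
  Y <- curves_as_matrix(curves, level)
  need <- unique(c(target, adjusters))
  ids <- intersect(rownames(Y), cohort$id)
  co <- cohort[match(ids, cohort$id), , drop = FALSE]
  cc <- stats::complete.cases(co[, need, drop = FALSE])
  n_drop <- (nrow(Y) - length(ids)) + sum(!cc)
  if (n_drop > 0)
    message(n_drop, " subject(s) dropped listwise (missing covariates/curves)")
  co <- co[cc, , drop = FALSE]
  Y <- Y[co$id, , drop = FALSE]
  if (nrow(Y) < 20L)
    warning("fewer than 20 subjects; RFT approximation may be poor")
  X <- spm_design(co, target, adjusters)
  fit <- fit_glm_field(Y, X, target)
  fwhm <- estimate_fwhm(fit$residuals)
  L <- ncol(Y) - 1
  t_crit <- rft_threshold(fit$df, fwhm, field_length = L, alpha = alpha,
                          tails = tails)
  cl <- extract_clusters(fit$t_field, t_crit, grid = 0:L,
                         nu = fit$df, fwhm = fwhm)
  structure(list(t_field = fit$t_field, df = fit$df, fwhm = fwhm,
                 resels = max(L - fwhm, 0) / fwhm, t_crit = t_crit,
                 clusters = cl, alpha = alpha, tails = tails,
                 target = target, level = level, n = nrow(Y),
                 n_dropped = n_drop),
            class = "spm_result")
}

curves_as_matrix <- function(curves, level) {
  if (is.matrix(curves)) return(curves)
  stopifnot(is.data.frame(curves))
  cv <- curves[curves$level == level, , drop = FALSE]
  if (nrow(cv) == 0L) stop("no curves at level ", level)
  ids <- unique(cv$subject)
  Y <- matrix(NA_real_, length(ids), 101L, dimnames = list(ids, NULL))
  for (id in ids) {
    r <- cv[cv$subject == id, ]
    Y[id, r$node_pct + 1L] <- r$fi
  }
  Y
}

#' @method print spm_result
#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("SPM{t} for %s at %s (n=%d, df=%d, %d-tailed alpha=%.3f)\n",
              x$target, x$level, x$n, x$df, x$tails, x$alpha))
  cat(sprintf("  FWHM = %.2f%%, resels = %.2f, t_crit = %.3f\n",
              x$fwhm, x$resels, x$t_crit))
  if (nrow(x$clusters) == 0L) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      cat(sprintf("  cluster %d: %.1f%% to %.1f%% (sign %+d, peak t = %.2f, p = %.4f)\n",
                  i, cl$start_pct, cl$end_pct, cl$sign, cl$peak_t, cl$p))
    }
  }
  invisible(x)
}

#' Serialize an SPM result to a machine-readable cluster report
#'
#' @param x an `spm_result`.
#' @param path optional file to write JSON to.
#' @return the report as a list (invisibly if written to file).
#' @export
spm_report <- function(x, path = NULL) {
  rep <- list(level = x$level, target = x$target, alpha = x$alpha,
              tails = x$tails, n = x$n, df = x$df, fwhm = x$fwhm,
              t_crit = x$t_crit,
              clusters = x$clusters[, c("start_pct", "end_pct", "sign",
                                        "peak_t", "p")])
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(rep))
  }
  rep
}
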