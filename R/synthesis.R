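#' Covariate-linked spatial effect specification
#'
#' Describes a known ground-truth association injected into synthetic
#' fat-fraction data: within a depth window (percent of radial muscle
#' width, 0 = deepest), pixel/node fat fraction shifts by
#' `sign * slope * z` FI% where `z` is the subject's standardized value of
#' the target covariate.
#'
#' @param target_covariate column name in the cohort table
#'   (e.g. "chronicity_yr", "met_min_wk").
#' @param depth_window numeric pair in `[0, 100]`, start < end.
#' @param slope FI% change per 1 SD of the covariate (>= 0).
#' @param level `"L4L5"`, `"L5S1"` or `"both"`.
#' @param sign `+1` or `-1`, the direction of the association.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(target_covariate, depth_window, slope,
                        level = "both", sign = 1) {
  stopifnot(is.character(target_covariate), length(depth_window) == 2L)
  if (any(!is.finite(depth_window)) || depth_window[1] >= depth_window[2] ||
      depth_window[1] < 0 || depth_window[2] > 100)
    stop("depth_window must satisfy 0 <= start < end <= 100")
  if (!level %in% c("L4L5", "L5S1", "both")) stop("bad level")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  structure(list(target_covariate = target_covariate,
                 depth_window = as.numeric(depth_window),
                 slope = as.numeric(slope),
                 level = level, sign = sign),
            class = "effect_spec")
}

#' Linear deep-to-superficial baseline fat profile
#'
#' The default radial fat-infiltration profile used by the synthetic
#' generators: FI% declines linearly from the deep muscle (adjacent to the
#' vertebral center of rotation) to the superficial border, the dominant
#' gradient seen in multifidus fat maps of cLBP cohorts.
#'
#' @param deep FI% at 0% depth (deepest).
#' @param superficial FI% at 100% depth (most superficial).
#' @return a function mapping depth percent in `[0, 100]` to FI%.
#' @export
baseline_profile <- function(deep = 45, superficial = 15) {
  force(deep); force(superficial)
  function(depth_pct) deep + (superficial - deep) * depth_pct / 100
}

as_baseline_fun <- function(baseline) {
  if (is.function(baseline)) return(baseline)
  if (is.numeric(baseline) && length(baseline) == 101L)
    return(stats::approxfun(0:100, baseline, rule = 2))
  stop("baseline must be a function of depth percent or a 101-node vector")
}

# Smooth 1D Gaussian random curves: white noise convolved with a Gaussian
# kernel of the requested FWHM (grid units), normalized to unit marginal
# variance at every node before scaling by `sd`.
smooth_gaussian_curves <- function(n, fwhm, sd = 1, n_nodes = 101L) {
  stopifnot(n >= 1, fwhm > 0, sd >= 0)
  sk <- fwhm / (2 * sqrt(2 * log(2)))
  pad <- max(1L, ceiling(4 * sk))
  m <- n_nodes + 2L * pad
  offs <- -pad:pad
  kern <- exp(-offs^2 / (2 * sk^2))
  W <- matrix(stats::rnorm(n * m), n, m)
  K <- matrix(0, m, n_nodes)
  for (j in seq_len(n_nodes)) {
    rows <- j + pad + offs
    K[rows, j] <- kern
  }
  K <- sweep(K, 2, sqrt(colSums(K^2)), "/")
  sd * (W %*% K)
}

# Standardized (z-scored) continuous covariates of a cohort table; a
# zero-variance covariate standardizes to 0.
cohort_zscores <- function(cohort) {
  cols <- c("age", "bmi", "pain_nrs", "chronicity_yr", "met_min_wk")
  z <- sapply(cols, function(cl) {
    x <- cohort[[cl]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  z <- matrix(z, nrow = nrow(cohort),
              dimnames = list(cohort$id, cols))
  z
}

default_geometry <- function() {
  list(dim = c(80L, 80L), cor = c(30, 40.5),
       r_inner = 10, r_outer = 38,
       angle_left = c(15, 75), angle_right = c(-75, -15),
       pixel_spacing = 1)
}

# Binary half-annulus sector mask posterior to the CoR. Angles are degrees
# from the posterior (+row) axis; positive angles to the subject's left.
sector_mask <- function(dim, cor, r_inner, r_outer, angle_deg) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  dy <- rows - cor[1]
  dx <- cols - cor[2]
  d <- sqrt(dy^2 + dx^2)
  ang <- atan2(dx, dy) * 180 / pi  # 0 = posterior, +left, -right
  m <- d >= r_inner & d <= r_outer & ang >= angle_deg[1] & ang <= angle_deg[2]
  storage.mode(m) <- "integer"
  m
}

#' Render one synthetic axial fat-fraction slice for a subject
#'
#' Pixel FI% is the baseline radial profile evaluated at the pixel's
#' normalized depth (0% at the innermost in-mask radius from the center of
#' rotation, 100% at the outermost, per side), plus every active injected
#' effect (`sign * slope * z`), plus iid Gaussian noise, clipped to
#' `[0, 100]`. Left and right muscles get independent noise.
#'
#' @param cov_z named numeric vector of the subject's standardized
#'   covariates (cohort z-scores), e.g. from [cohort_zscores()].
#' @param geometry list with `dim`, `cor`, `r_inner`, `r_outer`,
#'   `angle_left`, `angle_right`, `pixel_spacing`; see `default_geometry`
#'   used by [simulate_cohort()].
#' @param baseline function of depth percent (or 101-node vector).
#' @param effects list of [effect_spec()] objects.
#' @param noise_sd per-pixel Gaussian noise SD in FI%.
#' @param level,slice_index slice identity tags.
#' @param seed integer seed; regeneration is bit-identical.
#' @return a [fat_fraction_slice()].
#' @export
render_muscle_slice <- function(cov_z, geometry, baseline = baseline_profile(),
                                effects = list(), noise_sd = 4,
                                level = "L4L5", slice_index = 1L, seed = 1L) {
  bfun <- as_baseline_fun(baseline)
  g <- geometry
  masks <- list(
    left = sector_mask(g$dim, g$cor, g$r_inner, g$r_outer, g$angle_left),
    right = sector_mask(g$dim, g$cor, g$r_inner, g$r_outer, g$angle_right)
  )
  if (any(vapply(masks, sum, numeric(1)) == 0))
    stop("mask geometry produced an empty mask")
  fat <- matrix(0, g$dim[1], g$dim[2])
  rows <- matrix(seq_len(g$dim[1]), g$dim[1], g$dim[2])
  cols <- matrix(seq_len(g$dim[2]), g$dim[1], g$dim[2], byrow = TRUE)
  d <- sqrt((rows - g$cor[1])^2 + (cols - g$cor[2])^2)
  with_seed(seed, {
    for (side in names(masks)) {
      idx <- which(masks[[side]] == 1L)
      dd <- d[idx]
      depth <- (dd - min(dd)) / (max(dd) - min(dd)) * 100
      val <- bfun(depth)
      for (ef in effects) {
        if (!ef$level %in% c(level, "both")) next
        z <- unname(cov_z[ef$target_covariate])
        if (is.na(z)) stop("unknown effect covariate: ", ef$target_covariate)
        act <- depth >= ef$depth_window[1] & depth <= ef$depth_window[2]
        val[act] <- val[act] + ef$sign * ef$slope * z
      }
      if (noise_sd > 0) val <- val + stats::rnorm(length(val), 0, noise_sd)
      fat[idx] <- pmin(100, pmax(0, val))
    }
  })
  fat_fraction_slice(fat = fat, masks = masks, cor = g$cor, level = level,
                     slice_index = slice_index,
                     pixel_spacing = g$pixel_spacing %||% 1)
}

#' Simulate a full synthetic imaging cohort
#'
#' Draws covariates from `spec` and renders, for every subject, two axial
#' slices at each of the two lumbar levels (L4L5, L5S1), each slice holding
#' independent left and right multifidus masks. Injected effects are the
#' exact ground truth against which downstream recovery is judged.
#'
#' @param spec a [covariate_spec()].
#' @param geometry slice geometry (see [render_muscle_slice()]); default
#'   an 80x80 raster, CoR at (30, 40.5), muscle spanning radii 10-38 px.
#' @param baseline radial baseline profile.
#' @param effects list of [effect_spec()].
#' @param noise_sd per-pixel noise SD in FI%.
#' @param seed global seed; per-slice child seeds are fanned out
#'   deterministically.
#' @return list with `cohort` (data.frame), `subjects` (per subject, a list
#'   of 4 [fat_fraction_slice()]s), and `truth` (the effect list).
#' @export
simulate_cohort <- function(spec = covariate_spec(), geometry = default_geometry(),
                            baseline = baseline_profile(), effects = list(),
                            noise_sd = 4, seed = spec$seed) {
  spec$seed <- child_seed(seed, 0L)
  cohort <- draw_covariates(spec)
  z <- cohort_zscores(cohort)
  levels_ <- c("L4L5", "L5S1")
  subjects <- vector("list", nrow(cohort))
  names(subjects) <- cohort$id
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    sl <- list()
    for (lv in levels_) for (si in 1:2) {
      k <- k + 1L
      sl[[paste(lv, si, sep = "_")]] <- render_muscle_slice(
        cov_z = z[i, ], geometry = geometry, baseline = baseline,
        effects = effects, noise_sd = noise_sd, level = lv,
        slice_index = si, seed = child_seed(seed, k))
    }
    subjects[[i]] <- sl
  }
  list(cohort = cohort, subjects = subjects, truth = effects)
}

#' Simulate a cohort of radial fat curves directly
#'
#' Curve-level counterpart of [simulate_cohort()] used for statistical
#' calibration studies where rendering rasters is unnecessary: each
#' subject's 101-node curve is the baseline profile plus injected
#' depth-window effects plus smooth Gaussian noise (FWHM in grid-percent
#' units), clipped to `[0, 100]` FI%.
#'
#' @param spec a [covariate_spec()] (its `n_subjects` sets the cohort size).
#' @param baseline profile function or 101-node vector.
#' @param effects list of [effect_spec()] applying to `level`.
#' @param noise_sd marginal SD of the curve noise in FI%.
#' @param noise_fwhm smoothness of the curve noise, grid-percent units.
#' @param level lumbar level tag attached to the curves.
#' @param seed integer seed.
#' @return list with `cohort`, `curves` (n x 101 matrix, rownames = subject
#'   ids, one row per subject at `level`), `level`, and `truth`.
#' @export
simulate_curve_cohort <- function(spec = covariate_spec(), baseline = baseline_profile(),
                                  effects = list(), noise_sd = 4,
                                  noise_fwhm = 10, level = "L4L5",
                                  seed = spec$seed) {
  spec$seed <- child_seed(seed, 0L)
  cohort <- draw_covariates(spec)
  z <- cohort_zscores(cohort)
  bfun <- as_baseline_fun(baseline)
  grid <- 0:100
  n <- nrow(cohort)
  Y <- matrix(rep(bfun(grid), each = n), n, 101L)
  for (ef in effects) {
    if (!ef$level %in% c(level, "both")) next
    zc <- z[, ef$target_covariate]
    act <- grid >= ef$depth_window[1] & grid <= ef$depth_window[2]
    Y[, act] <- Y[, act] + ef$sign * ef$slope * zc
  }
  if (noise_sd > 0)
    Y <- Y + with_seed(child_seed(seed, 1L),
                       smooth_gaussian_curves(n, fwhm = noise_fwhm, sd = noise_sd))
  Y[] <- pmin(100, pmax(0, Y))
  rownames(Y) <- cohort$id
  list(cohort = cohort, curves = Y, level = level, truth = effects)
}
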