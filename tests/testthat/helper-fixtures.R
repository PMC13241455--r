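# Fixtures and independent oracles shared across test files. Oracles here
# are deliberately written as plain brute-force loops, independent of the
# package's vectorized implementations.

# A slice whose in-mask fat is an arbitrary function of normalized depth
# (percent, per side), rendered through the package's geometry.
make_depth_slice <- function(depth_fun, noise_sd = 0, seed = 1,
                             level = "L4L5", geometry = NULL) {
  g <- geometry %||% fatmapr:::default_geometry()
  z <- c(age = 0, bmi = 0, pain_nrs = 0, chronicity_yr = 0, met_min_wk = 0)
  render_muscle_slice(z, g, baseline = depth_fun, effects = list(),
                      noise_sd = noise_sd, level = level, seed = seed)
}

# Random blob mask on a small raster; returns a fat_fraction_slice with
# uniform random fat values.
random_mask_slice <- function(seed, dim = c(24L, 24L)) {
  set.seed(seed)
  repeat {
    m <- matrix(as.integer(runif(prod(dim)) < 0.25), dim[1], dim[2])
    cor <- c(runif(1, 2, dim[1] - 1), runif(1, 2, dim[2] - 1))
    if (sum(m) >= 10L) break
  }
  fat <- matrix(0, dim[1], dim[2])
  fat[m == 1L] <- runif(sum(m), 0, 100)
  fat_fraction_slice(fat, list(left = m, right = m), cor, "L4L5", 1L)
}

# Brute-force ROI binning oracle: loops over every in-mask pixel and bins
# its Euclidean distance from the CoR into width-2 shells from r_min.
brute_force_rois <- function(slice, side) {
  m <- slice$masks[[side]]
  idx <- which(m == 1L)
  d <- numeric(length(idx))
  for (q in seq_along(idx)) {
    rc <- arrayInd(idx[q], dim(m))
    d[q] <- sqrt((rc[1] - slice$cor[1])^2 + (rc[2] - slice$cor[2])^2)
  }
  r_min <- min(d)
  bins <- floor((d - r_min) / 2)
  lapply(0:max(bins), function(k) sort(idx[bins == k]))
}

# Permutation oracle for the familywise max-|t| threshold of the SPM
# t-field (Freedman-Lane style simple permutation of the target).
perm_max_t_threshold <- function(Y, cohort, target, nperm = 1000, seed = 1,
                                 prob = 0.95) {
  X <- spm_design(cohort, target)
  j <- match(target, colnames(X))
  Z <- X[, -j, drop = FALSE]
  x <- X[, j]
  qz <- qr(Z)
  RY <- qr.resid(qz, Y)
  ssY <- colSums(RY^2)
  n <- nrow(Y)
  nu <- n - ncol(X)
  set.seed(seed)
  mx <- replicate(nperm, {
    xs <- x[sample.int(n)]
    rx <- qr.resid(qz, xs)
    sxx <- sum(rx^2)
    b <- as.vector(crossprod(rx, RY)) / sxx
    ssr <- ssY - b^2 * sxx
    max(abs(b / sqrt(ssr / (nu * sxx))))
  })
  unname(stats::quantile(mx, prob))
}

# Jaccard overlap between a detected cluster and a truth depth window.
jaccard_window <- function(start, end, truth) {
  inter <- max(0, min(end, truth[2]) - max(start, truth[1]))
  uni <- max(end, truth[2]) - min(start, truth[1])
  inter / uni
}

# Best Jaccard of any same-sign detected cluster against the truth window.
best_recovery_jaccard <- function(clusters, truth, sign = 1) {
  cl <- clusters[clusters$sign == sign, , drop = FALSE]
  if (nrow(cl) == 0L) return(0)
  max(mapply(jaccard_window, cl$start_pct, cl$end_pct,
             MoreArgs = list(truth = truth)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
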