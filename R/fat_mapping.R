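#' One segmented axial fat-fraction slice
#'
#' Container for a 2D fat-fraction raster (percent fat per pixel), binary
#' left/right multifidus masks, the continuous center-of-rotation (CoR)
#' coordinate of the motion segment, and slice identity tags. Masks exclude
#' epimuscular fat by construction (segmentation is an input, not computed
#' here).
#'
#' @param fat numeric matrix, FI% in `[0, 100]` (finite in-mask).
#' @param masks named list of 0/1 integer matrices (`left`, `right`), same
#'   dimensions as `fat`, each nonempty.
#' @param cor numeric `(row, col)` coordinate, inside the raster bounds.
#' @param level `"L4L5"` or `"L5S1"`.
#' @param slice_index 1 or 2.
#' @param pixel_spacing physical length per pixel (default 1).
#' @return object of class `fat_fraction_slice`.
#' @export
fat_fraction_slice <- function(fat, masks, cor, level, slice_index,
                               pixel_spacing = 1) {
  stopifnot(is.matrix(fat), is.list(masks), length(cor) == 2L)
  if (cor[1] < 1 || cor[1] > nrow(fat) || cor[2] < 1 || cor[2] > ncol(fat))
    stop("cor must lie inside the raster bounds")
  if (!level %in% c("L4L5", "L5S1")) stop("level must be L4L5 or L5S1")
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!all(dim(m) == dim(fat))) stop("mask dimensions must match raster")
    if (sum(m) == 0) stop("mask '", nm, "' is empty")
    v <- fat[m == 1L]
    if (any(!is.finite(v))) stop("non-finite fat values inside mask '", nm, "'")
    if (any(v < 0 | v > 100)) stop("in-mask fat values must lie in [0, 100]")
  }
  structure(list(fat = fat, masks = masks, cor = as.numeric(cor),
                 level = level, slice_index = as.integer(slice_index),
                 pixel_spacing = pixel_spacing),
            class = "fat_fraction_slice")
}

mask_distances <- function(slice, side) {
  m <- slice$masks[[side]]
  if (is.null(m)) stop("no mask for side '", side, "'")
  idx <- which(m == 1L)
  rc <- arrayInd(idx, dim(m))
  d <- sqrt((rc[, 1] - slice$cor[1])^2 + (rc[, 2] - slice$cor[2])^2)
  list(idx = idx, d = d)
}

#' Radial regions of interest at two-pixel increments from the CoR
#'
#' Partitions the in-mask pixels of one side into non-overlapping distance
#' shells of width 2 pixels radiating outward from the center of rotation.
#' Shell k (k = 0, 1, ...) contains the pixels whose Euclidean distance d
#' from the CoR satisfies `r_min + 2k <= d < r_min + 2(k+1)`, where `r_min`
#' is the minimum in-mask distance. Increments are in acquisition-grid
#' pixel units regardless of `pixel_spacing`.
#'
#' @param slice a [fat_fraction_slice()].
#' @param side `"left"` or `"right"`.
#' @return list of integer vectors of raster indices, one per shell
#'   (possibly empty for interior gaps); attributes `r_min`, `r_max` carry
#'   the in-mask distance range. Union of shells = mask; shells disjoint.
#' @export
radial_rois <- function(slice, side) {
  md <- mask_distances(slice, side)
  r_min <- min(md$d); r_max <- max(md$d)
  if (r_max - r_min < .Machine$double.eps^0.5) {
    warning("all in-mask pixels at a single distance; one ROI")
    rois <- list(md$idx)
  } else {
    bin <- floor((md$d - r_min) / 2)
    nbin <- max(bin) + 1L
    rois <- lapply(seq_len(nbin) - 1L, function(k) md$idx[bin == k])
  }
  attr(rois, "r_min") <- r_min
  attr(rois, "r_max") <- r_max
  rois
}

new_radial_curve <- function(fi, subject = NA_character_, level = NA_character_,
                             n_pixels = NULL, flags = character(0)) {
  stopifnot(length(fi) == 101L)
  structure(list(grid = 0:100, fi = as.numeric(fi),
                 n_pixels_per_roi = n_pixels, subject = subject,
                 level = level, flags = flags),
            class = "radial_fat_curve")
}

#' Distance-normalized radial fat distribution curve for one muscle side
#'
#' Computes the mean FI% in each radial ROI, places it at the ROI's
#' mid-depth (the mean in-mask radial distance of its pixels), normalizes
#' depth to 0-100% of the radial muscle width (min to max in-mask
#' distance), and linearly interpolates onto the common 101-node grid
#' (integer percent). Grid nodes deeper than the first ROI or more
#' superficial than the last take the nearest ROI's value (no
#' extrapolation). Empty interior shells are bridged by interpolation with
#' a warning.
#'
#' @param slice a [fat_fraction_slice()].
#' @param side `"left"` or `"right"`.
#' @return a `radial_fat_curve` (101 nodes, 0% = deepest).
#' @export
roi_curve <- function(slice, side) {
  rois <- radial_rois(slice, side)
  md <- mask_distances(slice, side)
  d_by_idx <- stats::setNames(md$d, md$idx)
  r_min <- attr(rois, "r_min"); r_max <- attr(rois, "r_max")
  counts <- lengths(rois)
  if (any(counts == 0L))
    warning(sum(counts == 0L), " empty interior ROI(s); interpolating across")
  keep <- which(counts > 0L)
  if (length(keep) < 2L) {
    # single occupied shell: flat curve at its mean
    val <- mean(slice$fat[rois[[keep]]])
    return(new_radial_curve(rep(val, 101L), level = slice$level,
                            n_pixels = counts, flags = "single_roi"))
  }
  depth_pct <- vapply(rois[keep], function(ix)
    (mean(d_by_idx[as.character(ix)]) - r_min) / (r_max - r_min) * 100,
    numeric(1))
  mean_fi <- vapply(rois[keep], function(ix) mean(slice$fat[ix]), numeric(1))
  fi <- stats::approx(depth_pct, mean_fi, xout = 0:100, rule = 2)$y
  new_radial_curve(fi, level = slice$level, n_pixels = counts)
}

#' Average radial curves across sides and slices
#'
#' Node-wise unweighted mean of the supplied curves (normally left + right
#' x 2 slices for one subject and lumbar level, yielding the subject's one
#' fat-map at that level). Missing curves are tolerated: the mean of the
#' available curves is returned with an `"incomplete"` flag.
#'
#' @param curves list of `radial_fat_curve` objects on the common grid.
#' @param subject,level identity tags for the result.
#' @return a `radial_fat_curve`.
#' @export
average_curves <- function(curves, subject = NA_character_,
                           level = NA_character_) {
  curves <- Filter(Negate(is.null), curves)
  if (length(curves) == 0L) stop("no curves to average")
  M <- do.call(rbind, lapply(curves, `[[`, "fi"))
  flags <- if (length(curves) < 4L) "incomplete" else character(0)
  new_radial_curve(colMeans(M), subject = subject, level = level,
                   flags = flags)
}

#' Overall fat infiltration of the muscle cross-section
#'
#' Pixel-weighted mean FI% pooled over all in-mask pixels of both sides of
#' all supplied slices (one subject, one lumbar level).
#'
#' @param slices list of [fat_fraction_slice()] objects.
#' @return scalar FI% in `[0, 100]`.
#' @export
overall_fi <- function(slices) {
  if (inherits(slices, "fat_fraction_slice")) slices <- list(slices)
  vals <- unlist(lapply(slices, function(s)
    lapply(names(s$masks), function(sd) s$fat[s$masks[[sd]] == 1L])))
  mean(vals)
}

#' Deep-15 fat infiltration from a radial curve
#'
#' Mean FI% over the deepest 15% of the radial muscle width, i.e. curve
#' nodes at 0..15% inclusive (16 nodes) measured from the vertebral CoR.
#'
#' @param curve a `radial_fat_curve`.
#' @return scalar FI%.
#' @export
deep15_fi <- function(curve) {
  stopifnot(inherits(curve, "radial_fat_curve"))
  mean(curve$fi[curve$grid <= 15])
}

#' Subject-level curves and FI metrics for a simulated or loaded cohort
#'
#' For each subject and lumbar level, averages the four side x slice radial
#' curves into one fat-map and computes overall FI% (pooled pixels) and
#' deep15 FI%.
#'
#' @param subjects named list (by subject id) of per-subject slice lists,
#'   as produced by [simulate_cohort()] or [read_cohort_slices()].
#' @return list with `curves` — long data.frame (subject, level, node_pct,
#'   fi) — and `metrics` — data.frame (subject, level, overall_fi,
#'   deep15_fi).
#' @export
extract_cohort_curves <- function(subjects) {
  rows <- list(); mets <- list(); k <- 0L
  for (id in names(subjects)) {
    sl <- subjects[[id]]
    lv_of <- vapply(sl, `[[`, character(1), "level")
    for (lv in unique(lv_of)) {
      ss <- sl[lv_of == lv]
      cs <- unlist(lapply(ss, function(s)
        lapply(names(s$masks), function(sd) roi_curve(s, sd))),
        recursive = FALSE)
      avg <- average_curves(cs, subject = id, level = lv)
      k <- k + 1L
      rows[[k]] <- data.frame(subject = id, level = lv, node_pct = 0:100,
                              fi = avg$fi, stringsAsFactors = FALSE)
      mets[[k]] <- data.frame(subject = id, level = lv,
                              overall_fi = overall_fi(ss),
                              deep15_fi = deep15_fi(avg),
                              stringsAsFactors = FALSE)
    }
  }
  list(curves = do.call(rbind, rows), metrics = do.call(rbind, mets))
}

#' @method print radial_fat_curve
#' @export
print.radial_fat_curve <- function(x, ...) {
  cat(sprintf("<radial_fat_curve> subject=%s level=%s mean FI%%=%.1f deep15=%.1f\n",
              x$subject, x$level, mean(x$fi), mean(x$fi[x$grid <= 15])))
  invisible(x)
}
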