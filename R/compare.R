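#' Voxelwise percent dose-difference map
#'
#' Delta-D = (D_test - D_ref) / D_ref * 100, evaluated where the reference
#' dose is positive; elsewhere (air, unirradiated voxels) the difference is
#' NA and excluded from all downstream statistics.
#'
#' @param d_test,d_ref `dose_grid`s (or `voxel_volume`s of dose) on the same
#'   grid.
#' @return `voxel_volume` of percent differences (NA outside the evaluable
#'   region).
#' @export
dose_difference_map <- function(d_test, d_ref) {
  vt <- if (inherits(d_test, "dose_grid")) d_test$dose else d_test
  vr <- if (inherits(d_ref, "dose_grid")) d_ref$dose else d_ref
  if (!all(dim(vt$values) == dim(vr$values))) stop("dose grid shape mismatch")
  delta <- array(NA_real_, dim(vt$values))
  ok <- vr$values > 0
  delta[ok] <- (vt$values[ok] - vr$values[ok]) / vr$values[ok] * 100
  out <- vr
  out$values <- delta
  out$quantity <- "other"
  out
}

#' Per-ROI statistics of a difference map
#'
#' Mean and standard deviation of the voxelwise percent difference over each
#' mask, eroded to avoid boundary regions; NA voxels (zero reference dose)
#' are dropped.
#'
#' @param delta_map `voxel_volume` from [dose_difference_map()].
#' @param masks Named list of logical arrays.
#' @param erosion_mm Erosion radius in mm (default 0.3).
#' @return Data frame with `roi`, `mean`, `sd`, `n_voxels`.
#' @export
roi_dose_stats <- function(delta_map, masks, erosion_mm = 0.3) {
  out <- lapply(names(masks), function(nm) {
    m <- erode_mask(masks[[nm]], delta_map$spacing, erosion_mm)
    v <- delta_map$values[m]
    v <- v[is.finite(v)]
    if (!length(v)) stop("eroded ROI '", nm, "' has no evaluable voxels")
    data.frame(roi = nm, mean = mean(v), sd = sd(v), n_voxels = length(v))
  })
  do.call(rbind, out)
}

#' Fraction of misassigned voxels between two material maps
#'
#' Labels are compared by material name (palettes may be ordered
#' differently). Also tabulates the confusion matrix of reference versus
#' test materials over the region.
#'
#' @param map_test,map_ref `material_map`s on the same grid.
#' @param region Optional logical array restricting the comparison.
#' @return List with `fraction` (of differing voxels), `n` and `confusion`
#'   (table, reference in rows).
#' @export
misassignment_fraction <- function(map_test, map_ref, region = NULL) {
  if (!all(dim(map_test$labels$values) == dim(map_ref$labels$values)))
    stop("material map shape mismatch")
  nt <- map_test$palette[map_test$labels$values]
  nr <- map_ref$palette[map_ref$labels$values]
  if (!is.null(region)) { nt <- nt[region]; nr <- nr[region] }
  list(fraction = mean(nt != nr), n = length(nt),
       confusion = table(reference = nr, test = nt))
}

#' Histogram of voxelwise dose disagreement
#'
#' Bins the voxelwise percent dose differences of one or more methods over a
#' common region, with half-open bins \[lo, hi). Reports, per method, the
#' fraction of voxels in the bin containing zero error (default bin width 5
#' percentage points, i.e. |Delta-D| < 2.5).
#'
#' @param delta_maps Named list of difference maps ([dose_difference_map()]).
#' @param region Logical array (e.g. union of insert masks).
#' @param breaks Bin edges in percent (default `seq(-102.5, 102.5, by = 5)`,
#'   values outside are clamped into the end bins).
#' @return List with `breaks`, `counts` (matrix, one row per method) and
#'   `zero_bin_fraction` (named vector).
#' @export
dose_error_histogram <- function(delta_maps, region,
                                 breaks = seq(-102.5, 102.5, by = 5)) {
  stopifnot(!is.null(names(delta_maps)))
  counts <- t(vapply(delta_maps, function(dm) {
    v <- dm$values[region]
    v <- v[is.finite(v)]
    v <- pmin(pmax(v, breaks[1]), breaks[length(breaks)] - 1e-9)
    tabulate(findInterval(v, breaks, rightmost.closed = FALSE),
             nbins = length(breaks) - 1)
  }, numeric(length(breaks) - 1)))
  zero_bin <- findInterval(0, breaks)
  zf <- counts[, zero_bin] / rowSums(counts)
  list(breaks = breaks, counts = counts,
       zero_bin_fraction = stats::setNames(zf, names(delta_maps)))
}

#' Cumulative dose-volume histogram of a structure
#'
#' Computes the cumulative DVH over a structure mask and the standard
#' metrics: Dx is the minimum dose received by the hottest x% of the
#' structure volume, evaluated as the interpolated (1 - x/100) quantile of
#' the voxel doses (type-7 order statistics), plus mean and maximum dose.
#'
#' @param dose A `dose_grid` or `voxel_volume` of dose (Gy).
#' @param mask Logical array (non-empty).
#' @param structure Structure name.
#' @param n_bins Number of dose bins for the curve.
#' @return A `dvh_result`: `structure`, `dose_bins` (Gy),
#'   `cumulative_volume_fraction`, and `metrics` (named vector with `D95`,
#'   `D5`, `D1`, `mean`, `max`).
#' @export
compute_dvh <- function(dose, mask, structure = "structure", n_bins = 200) {
  v <- if (inherits(dose, "dose_grid")) dose$dose$values else dose$values
  if (!any(mask)) stop("empty structure mask")
  d <- v[mask]
  qs <- quantile(d, c(0.05, 0.95, 0.99), type = 7, names = FALSE)
  metrics <- c(D95 = qs[1], D5 = qs[2], D1 = qs[3], mean = mean(d), max = max(d))
  bins <- seq(0, max(d) * 1.001 + 1e-12, length.out = n_bins + 1)
  cvf <- vapply(bins, function(b) mean(d >= b), numeric(1))
  structure(list(structure = structure, dose_bins = bins,
                 cumulative_volume_fraction = cvf, metrics = metrics),
            class = "dvh_result")
}

#' @export
print.dvh_result <- function(x, ...) {
  cat("<dvh_result>", x$structure, "\n")
  print(round(x$metrics, 3))
  invisible(x)
}

#' Count distinct high-dose plateau levels of a structure
#'
#' Identifies the number of distinct dose levels ("plateaus" in the
#' cumulative DVH) above a threshold by counting modes of the kernel density
#' of the structure's voxel doses carrying at least `min_mass` of the
#' structure volume. Used to detect the multi-level bone dose structure that
#' multi-bone segmentations produce under kV irradiation.
#'
#' @param dose `dose_grid` or dose `voxel_volume`.
#' @param mask Structure mask.
#' @param above Only doses above this value (Gy) are considered (default the
#'   2 Gy prescription).
#' @param min_mass Minimum fraction of the considered voxels a mode must
#'   carry (default 0.05).
#' @return Integer number of distinct dose levels.
#' @export
count_dose_plateaus <- function(dose, mask, above = 2, min_mass = 0.05) {
  v <- if (inherits(dose, "dose_grid")) dose$dose$values else dose$values
  d <- v[mask]
  d <- d[d > above]
  if (length(d) < 20) return(0L)
  bw <- diff(range(d)) / 25
  if (bw <= 0) return(1L)
  de <- density(d, bw = bw, n = 512)
  y <- de$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  if (!length(peaks)) return(1L)
  # mass attribution: split at minima between consecutive peaks
  mins <- which(diff(sign(diff(y))) == 2) + 1
  cuts <- c(min(d) - 1e-9, de$x[mins], max(d) + 1e-9)
  masses <- tabulate(findInterval(d, sort(cuts)), nbins = length(cuts) - 1)
  sum(masses / length(d) >= min_mass)
}
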