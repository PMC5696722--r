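#' Per-material ROI statistics of a CT image
#'
#' Mean and standard deviation of the voxel values over each ground-truth
#' region of the phantom, with the region masks eroded by a physical margin
#' to exclude boundary (partial-volume) voxels. For the cylindrical phantoms
#' the regions are the twelve inserts plus the Solid Water bulk; multiple
#' inserts of the same material are pooled.
#'
#' @param image A `voxel_volume` co-registered with `phantom`.
#' @param phantom The ground-truth `phantom_model`.
#' @param erosion_mm Erosion radius in mm (default 0.3).
#' @return Data frame with columns `material`, `mean`, `sd`, `n_voxels`.
#' @export
roi_statistics <- function(image, phantom, erosion_mm = 0.3) {
  stopifnot(all(dim(image$values) == dim(phantom$labels$values)))
  sp <- image$spacing
  regions <- list()
  st <- phantom$structures
  ins <- grep("^insert_", names(st), value = TRUE)
  if (length(ins)) {
    for (k in seq_along(ins)) {
      mat <- phantom$palette[2 + k]
      regions[[mat]] <- if (is.null(regions[[mat]])) st[[ins[k]]]
                        else regions[[mat]] | st[[ins[k]]]
    }
    regions[["Solid Water"]] <- if (is.null(regions[["Solid Water"]]))
      st$bulk else regions[["Solid Water"]] | st$bulk
  } else {
    for (i in seq_along(phantom$palette))
      regions[[phantom$palette[i]]] <- phantom$labels$values == i
  }
  out <- lapply(names(regions), function(mat) {
    m <- erode_mask(regions[[mat]], sp, erosion_mm)
    if (!any(m)) stop("eroded ROI for '", mat, "' is empty")
    v <- image$values[m]
    data.frame(material = mat, mean = mean(v), sd = sd(v), n_voxels = sum(m))
  })
  do.call(rbind, out)
}

#' Build the piecewise bi-linear HU-density calibration curve
#'
#' Two least-squares linear segments joined (pinned) at the water point
#' (0 HU, 1.000 g/cm^3): one fitted over calibration media with mean HU in
#' (-900, 0] (air is represented by the explicit clamp instead), one over
#' media with mean HU >= 0. Queries at or below -1000 HU return the air
#' density; densities are clamped non-negative.
#'
#' @param roi_stats Data frame from [roi_statistics()] (columns `material`,
#'   `mean`) for the calibration phantom.
#' @param materials Named list of [material()] objects resolving the ROI
#'   material names.
#' @return An object of class `hu_rho_curve`.
#' @export
build_hu_rho_curve <- function(roi_stats, materials = load_materials()) {
  rho <- vapply(roi_stats$material, function(nm) {
    m <- materials[[nm]]
    if (is.null(m)) stop("unknown material '", nm, "'")
    m$mass_density
  }, numeric(1))
  hu <- roi_stats$mean
  if (length(hu) < 3) stop("need at least 3 calibration materials")
  slope_c <- function(h, r) sum(h * (r - 1)) / sum(h^2)  # pinned at (0, 1)
  # air is handled by the explicit (-1000, rho_air) clamp, not the fit: its
  # extreme leverage would otherwise drag the soft-tissue segment far off
  lo <- hu <= 0 & hu > -900; hi <- hu >= 0
  if (!any(lo) || !any(hi)) {
    warning("media on one side of the water joint only; single segment")
    s <- slope_c(hu, rho)
    slopes <- c(low = s, high = s)
  } else {
    slopes <- c(low = slope_c(hu[lo], rho[lo]), high = slope_c(hu[hi], rho[hi]))
  }
  rho_air <- if ("Air" %in% roi_stats$material) materials[["Air"]]$mass_density
             else 0.001
  structure(list(slope_low = unname(slopes["low"]),
                 slope_high = unname(slopes["high"]),
                 rho_air = rho_air,
                 nodes = data.frame(hu = c(-1000, 0, max(hu)),
                                    rho = c(rho_air, 1,
                                            1 + slopes["high"] * max(hu)))),
            class = "hu_rho_curve")
}

#' Evaluate an HU-density curve
#' @param curve A `hu_rho_curve`.
#' @param hu Numeric HU values.
#' @return Densities in g/cm^3.
#' @export
predict_density <- function(curve, hu) {
  rho <- ifelse(hu <= 0, 1 + curve$slope_low * hu, 1 + curve$slope_high * hu)
  rho[hu <= -1000] <- curve$rho_air
  pmax(rho, 0)
}

#' Convert an HU image to a density map
#' @param image `voxel_volume` of HU.
#' @param curve A `hu_rho_curve` from [build_hu_rho_curve()].
#' @return `voxel_volume` of density (g/cm^3).
#' @export
hu_to_density <- function(image, curve) {
  voxel_volume(array(predict_density(curve, image$values), dim = dim(image$values)),
               image$spacing, image$origin, quantity = "density")
}

#' Midpoint HU thresholds between consecutive media
#'
#' Automates the boundary choice: the threshold between two consecutive media
#' is the midpoint of their mean HU values. The media list must be ordered by
#' increasing mean HU.
#'
#' @param roi_stats Data frame with `material` and `mean` columns.
#' @param media Ordered character vector of media names.
#' @return Numeric vector of length `length(media) - 1`.
#' @export
default_boundaries <- function(roi_stats, media) {
  mu <- roi_stats$mean[match(media, roi_stats$material)]
  if (anyNA(mu)) stop("media missing from ROI statistics: ",
                      paste(media[is.na(mu)], collapse = ", "))
  if (is.unsorted(mu, strictly = TRUE))
    stop("media are not ordered by increasing mean HU")
  (mu[-1] + mu[-length(mu)]) / 2
}

#' Build a segmentation scheme
#'
#' Orders the media by their calibration mean HU and derives midpoint
#' thresholds, or accepts explicit thresholds.
#'
#' @param media Character vector of media names (or a preset name for
#'   [scheme_preset()]).
#' @param roi_stats ROI statistics providing mean HU per material (required
#'   unless `boundaries` is given).
#' @param boundaries Optional explicit strictly-increasing HU thresholds
#'   (length `length(media) - 1`), ordered like `media`.
#' @param name Scheme name.
#' @return An object of class `seg_scheme` with ordered `media` and
#'   `boundaries`.
#' @export
seg_scheme <- function(media, roi_stats = NULL, boundaries = NULL,
                       name = NULL) {
  if (length(media) == 1 && is.null(name)) { name <- media; media <- scheme_preset(media) }
  stopifnot(length(media) >= 2)
  if (is.null(boundaries)) {
    if (is.null(roi_stats)) stop("need roi_stats or explicit boundaries")
    mu <- roi_stats$mean[match(media, roi_stats$material)]
    if (anyNA(mu)) stop("media missing from ROI statistics: ",
                        paste(media[is.na(mu)], collapse = ", "))
    media <- media[order(mu)]
    boundaries <- default_boundaries(roi_stats, media)
  } else {
    if (length(boundaries) != length(media) - 1 ||
        is.unsorted(boundaries, strictly = TRUE))
      stop("boundaries must be strictly increasing, one fewer than media")
  }
  structure(list(name = if (is.null(name)) "custom" else name,
                 media = media, boundaries = boundaries),
            class = "seg_scheme")
}

#' Single-energy CT material segmentation
#'
#' Assigns to each voxel the scheme medium whose HU interval contains the
#' voxel value (intervals are half-open, extended to -Inf/+Inf at the ends),
#' and a mass density from the HU-density calibration curve. Air voxels are
#' flagged for exclusion from dose scoring.
#'
#' @param image `voxel_volume` of HU.
#' @param scheme A [seg_scheme()].
#' @param curve A `hu_rho_curve`.
#' @param materials Material database resolving the scheme media.
#' @return A `material_map`: list with `labels` (`voxel_volume`), `palette`
#'   (media names), `rho` (`voxel_volume` of density) and `score_mask`
#'   (logical array, FALSE in air).
#' @export
segment_sect <- function(image, scheme, curve, materials = load_materials()) {
  idx <- findInterval(image$values, scheme$boundaries) + 1L
  labels <- array(idx, dim = dim(image$values))
  rho <- hu_to_density(image, curve)
  material_map(labels, scheme$media, rho, image$spacing, image$origin,
               materials)
}

#' Construct a material map
#'
#' @param labels Integer 3-D array of palette indices.
#' @param palette Character vector of media names.
#' @param rho `voxel_volume` of density or numeric array.
#' @param spacing,origin Grid geometry (taken from `rho` when it is a
#'   `voxel_volume`).
#' @param materials Material database; every palette entry must resolve.
#' @return Object of class `material_map`.
#' @export
material_map <- function(labels, palette, rho, spacing = NULL, origin = c(0, 0, 0),
                         materials = load_materials()) {
  miss <- setdiff(palette, names(materials))
  if (length(miss)) stop("unknown media: ", paste(miss, collapse = ", "))
  if (inherits(rho, "voxel_volume")) {
    spacing <- rho$spacing; origin <- rho$origin
  } else {
    rho <- voxel_volume(rho, spacing, origin, quantity = "density")
  }
  lab <- voxel_volume(labels, spacing, origin, quantity = "label")
  score <- array(palette[labels] != "Air", dim = dim(labels))
  structure(list(labels = lab, palette = palette, rho = rho,
                 score_mask = score, materials = materials[palette]),
            class = "material_map")
}

#' @export
print.material_map <- function(x, ...) {
  tab <- table(factor(x$palette[x$labels$values], levels = x$palette))
  cat("<material_map>", paste(dim(x$labels$values), collapse = "x"), "voxels\n")
  print(round(tab / sum(tab), 4))
  invisible(x)
}

#' Ground-truth material map of a phantom
#'
#' The reference map: every voxel carries its true material and nominal
#' density. For the validation phantom the PMMA insert can be relabelled
#' Lucite and Teflon excluded, mirroring the reference-scheme conventions.
#'
#' @param phantom A `phantom_model`.
#' @param merge_pmma Relabel PMMA as Lucite (default TRUE when present).
#' @return A `material_map`.
#' @export
reference_material_map <- function(phantom, merge_pmma = TRUE) {
  palette <- phantom$palette
  labels <- phantom$labels$values
  rho_m <- vapply(palette, function(nm) phantom$materials[[nm]]$mass_density,
                  numeric(1))
  if (merge_pmma && all(c("PMMA", "Lucite") %in% palette)) {
    i_p <- which(palette == "PMMA"); i_l <- which(palette == "Lucite")
    labels[labels == i_p] <- i_l
  }
  rho <- array(rho_m[labels], dim = dim(labels))
  material_map(labels, palette, rho, phantom$labels$spacing,
               phantom$labels$origin, phantom$materials)
}
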