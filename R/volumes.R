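#' Voxel volumes
#'
#' A `voxel_volume` is a 3-D scalar grid with isotropic or anisotropic
#' spacing (mm), an origin (mm, position of the centre of voxel \[1,1,1\])
#' and a `quantity` tag (`"HU"`, `"density"`, `"rho_e"`, `"z_eff"`, `"dose"`
#' or `"label"`). Label volumes are integer-valued.
#'
#' @param values 3-D numeric array.
#' @param spacing Voxel spacing in mm, length 1 (isotropic) or 3.
#' @param origin Position of the first voxel centre in mm, length 3.
#' @param quantity Quantity tag.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0),
                         quantity = c("HU", "density", "rho_e", "z_eff",
                                      "dose", "label", "other")) {
  quantity <- match.arg(quantity)
  if (length(dim(values)) != 3) stop("values must be a 3-D array")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(all(spacing > 0), length(origin) == 3)
  if (quantity == "label") {
    if (any(values != round(values))) stop("label volume must be integer-valued")
    storage.mode(values) <- "integer"
  } else if (!all(is.finite(values))) stop("non-finite voxel values")
  structure(list(values = values, spacing = spacing, origin = origin,
                 quantity = quantity), class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume>", x$quantity, paste(dim(x$values), collapse = "x"),
      "@", paste(signif(x$spacing, 4), collapse = "x"), "mm\n")
  cat("  range:", paste(signif(range(x$values), 5), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

# voxel centre coordinates along each axis (mm)
.axis_coords <- function(vol) {
  d <- dim(vol$values)
  lapply(1:3, function(k) vol$origin[k] + (seq_len(d[k]) - 1) * vol$spacing[k])
}

#' Write / read volumes as NIfTI
#'
#' Thin wrappers around the RNifti package; spacing and origin are carried in
#' the NIfTI header. The quantity tag is not stored in the file and must be
#' supplied again on read.
#'
#' @param vol A [voxel_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values, reference = NULL)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param quantity Quantity tag for the volume read from `path`.
#' @export
read_volume <- function(path, quantity = "other") {
  img <- RNifti::readNifti(path)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               spacing = RNifti::pixdim(img)[1:3], quantity = quantity)
}

# separable Gaussian blur by shift-and-add convolution, replicated edges.
# fwhm in mm; returns the array unchanged when fwhm is 0.
.gaussian_blur3d <- function(arr, spacing, fwhm) {
  if (fwhm <= 0) return(arr)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    sig <- sigma_mm / spacing[axis]
    r <- max(1L, ceiling(3 * sig))
    k <- exp(-(seq(-r, r))^2 / (2 * sig^2)); k <- k / sum(k)
    arr <- .shift_convolve(arr, k, axis)
  }
  arr
}

# convolve along one axis with kernel k (odd length) using index shifts
.shift_convolve <- function(arr, k, axis) {
  d <- dim(arr); n <- d[axis]; r <- (length(k) - 1L) / 2L
  out <- array(0, d)
  idx_full <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
    idx <- idx_full; idx[[axis]] <- src
    out <- out + k[j] * arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  out
}

#' Downsample a volume, mask or material map by decimation
#'
#' Keeps every `factor`-th voxel along each axis (stride decimation, no
#' averaging, so labels stay valid); used to run dose calculations on a
#' coarser grid than the imaging/segmentation grid.
#'
#' @param x A `voxel_volume`, 3-D array (e.g. a mask) or `material_map`.
#' @param factor Integer decimation factor (default 2).
#' @return Object of the same kind on the coarser grid.
#' @export
downsample_volume <- function(x, factor = 2L) {
  factor <- as.integer(factor)
  if (inherits(x, "material_map")) {
    lab <- downsample_volume(x$labels, factor)
    rho <- downsample_volume(x$rho, factor)
    return(material_map(lab$values, x$palette, rho, materials = x$materials))
  }
  if (inherits(x, "voxel_volume")) {
    d <- dim(x$values)
    idx <- lapply(d, function(n) seq(1, n, by = factor))
    out <- x
    out$values <- x$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    out$spacing <- x$spacing * factor
    return(out)
  }
  d <- dim(x)
  x[seq(1, d[1], by = factor), seq(1, d[2], by = factor),
    seq(1, d[3], by = factor), drop = FALSE]
}

#' Erode a binary mask by a physical distance
#'
#' Morphological erosion with a spherical structuring element of the given
#' radius in mm; used to exclude boundary (partial-volume) voxels before
#' computing ROI statistics.
#'
#' @param mask 3-D logical array.
#' @param spacing Voxel spacing in mm (length 1 or 3).
#' @param mm Erosion radius in mm; `0` returns the mask unchanged.
#' @return Eroded logical array.
#' @export
erode_mask <- function(mask, spacing, mm) {
  if (mm <= 0) return(mask)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  r <- floor(mm / spacing)
  offs <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  dist <- sqrt((offs$i * spacing[1])^2 + (offs$j * spacing[2])^2 +
               (offs$k * spacing[3])^2)
  offs <- offs[dist <= mm + 1e-9, , drop = FALSE]
  d <- dim(mask)
  out <- mask
  padded <- array(FALSE, d + 2 * c(max(abs(offs$i)), max(abs(offs$j)), max(abs(offs$k))))
  p <- c(max(abs(offs$i)), max(abs(offs$j)), max(abs(offs$k)))
  padded[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]), p[3] + seq_len(d[3])] <- mask
  for (t in seq_len(nrow(offs))) {
    sl <- padded[p[1] + offs$i[t] + seq_len(d[1]),
                 p[2] + offs$j[t] + seq_len(d[2]),
                 p[3] + offs$k[t] + seq_len(d[3]), drop = FALSE]
    out <- out & sl
    if (!any(out)) break
  }
  out
}
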