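#' Phantom models
#'
#' A `phantom_model` bundles a ground-truth label volume, a palette mapping
#' label integers to materials, and named structure masks. It is the input to
#' the CT simulator and the reference against which segmentations and doses
#' are compared.
#'
#' @name phantom_model
NULL

.phantom_model <- function(labels, palette, materials, structures, spacing,
                           origin) {
  lab <- voxel_volume(labels, spacing, origin, quantity = "label")
  stopifnot(all(unique(as.vector(labels)) %in% seq_along(palette)))
  structure(list(labels = lab, palette = palette, materials = materials,
                 structures = structures), class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat("<phantom_model>", paste(dim(x$labels$values), collapse = "x"),
      "voxels @", signif(x$labels$spacing[1], 4), "mm\n")
  cat("  media:", paste(x$palette, collapse = ", "), "\n")
  cat("  structures:", paste(names(x$structures), collapse = ", "), "\n")
  invisible(x)
}

# material list for a phantom label index
phantom_material <- function(phantom, label) phantom$materials[[phantom$palette[label]]]

.insert_order <- list(
  calibration = c("AP6", "Solid Water", "IB3", "SR2", "CB2-30%", "BR12",
                  "Air", "Water", "B200", "LV1", "SB3", "CB2-50%"),
  validation = c("BR12", "Teflon", "Lucite", "Air", "PMMA", "Paraffin",
                 "Water", "Muscle", "Air", "Air", "Adipose", "Bone"))

#' Build a cylindrical mini-phantom
#'
#' A 3 cm diameter Solid Water cylinder with twelve 3.5 mm diameter
#' tissue-substitute inserts equally spaced on a 10.5 mm radius ring,
#' numbered clockwise from 12 o'clock. Two insert sets are available:
#' `"calibration"` (AP6, Solid Water, IB3, SR2, CB2-30%, BR12, Air, Water,
#' B200, LV1, SB3, CB2-50%) and `"validation"` (BR12, Teflon, Lucite, Air,
#' PMMA, Paraffin, Water, Muscle, Air, Air, Adipose, Bone).
#'
#' @param which `"calibration"` or `"validation"`.
#' @param spacing Isotropic voxel spacing in mm (must be <= 0.2 to resolve
#'   the 3.5 mm inserts; default 0.1034).
#' @param length_mm Cylinder length in mm (default 10; the analysis is
#'   translation-invariant along the axis, so short stacks are cheap
#'   surrogates).
#' @param margin_mm Air margin around the cylinder.
#' @return A `phantom_model` with structures `body`, `bulk` and
#'   `insert_1` .. `insert_12`.
#' @export
build_cylinder_phantom <- function(which = c("calibration", "validation"),
                                   spacing = 0.1034, length_mm = 10,
                                   margin_mm = 2) {
  which <- match.arg(which)
  if (spacing > 0.2) stop("spacing too coarse to resolve the 3.5 mm inserts")
  r_cyl <- 15; r_ring <- 10.5; r_ins <- 1.75
  ext <- r_cyl + margin_mm
  nxy <- ceiling(2 * ext / spacing); nz <- max(1L, round(length_mm / spacing))
  cx <- ((seq_len(nxy) - 1) - (nxy - 1) / 2) * spacing
  X <- matrix(cx, nxy, nxy); Y <- matrix(cx, nxy, nxy, byrow = TRUE)
  R2 <- X^2 + Y^2

  inserts <- .insert_order[[which]]
  mats <- load_materials()
  palette <- c("Air", "Solid Water", inserts)
  sl <- matrix(1L, nxy, nxy)          # air background
  sl[R2 <= r_cyl^2] <- 2L             # Solid Water bulk
  ins_masks2d <- vector("list", 12)
  for (k in 1:12) {
    ang <- (90 - (k - 1) * 30) * pi / 180  # clockwise from 12 o'clock
    d2 <- (X - r_ring * cos(ang))^2 + (Y - r_ring * sin(ang))^2
    m <- d2 <= r_ins^2
    if (!any(m)) stop("spacing too coarse to resolve the inserts")
    sl[m] <- k + 2L
    ins_masks2d[[k]] <- m
  }
  labels <- array(rep(sl, nz), dim = c(nxy, nxy, nz))
  rep3d <- function(m) array(rep(m, nz), dim = c(nxy, nxy, nz))
  structures <- c(list(body = rep3d(R2 <= r_cyl^2), bulk = rep3d(sl == 2L)),
                  stats::setNames(lapply(ins_masks2d, rep3d),
                                  paste0("insert_", 1:12)))
  .phantom_model(labels, palette, mats[unique(palette)], structures,
                 spacing, origin = c(cx[1], cx[1], -(nz - 1) / 2 * spacing))
}

#' Build a digital rodent-head phantom
#'
#' An idealized ellipsoidal head built from the six ICRU Report 44 tissues:
#' a Brain ellipsoid inside a Cranium shell, an ICRU Adipose outer layer, a
#' Spongiosa vertebra enclosing a spinal-cord canal (Brain composition), two
#' small Cortical Bone ossicle spheres, and an Air background. A fictitious
#' spherical tumour mask overlaps both the brain and the spinal cord. This is
#' a synthetic stand-in for a real specimen scan; it reproduces the topology
#' (OAR enclosed by bone, tumour straddling brain and cord), not mouse
#' anatomy.
#'
#' @param spacing Isotropic voxel spacing in mm (<= 0.3; default 0.2).
#' @return A `phantom_model` with structures `body`, `tumour`, `brain`,
#'   `spinal_cord` and `bone`.
#' @export
build_rodent_head_phantom <- function(spacing = 0.2) {
  if (spacing > 0.3) stop("spacing too coarse for the rodent head model")
  ext <- 11
  n <- ceiling(2 * ext / spacing)
  cx <- ((seq_len(n) - 1) - (n - 1) / 2) * spacing
  X <- array(cx, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))

  ellip <- function(c0, s) ((X - c0[1]) / s[1])^2 + ((Y - c0[2]) / s[2])^2 +
    ((Z - c0[3]) / s[3])^2 <= 1
  head <- ellip(c(0, 0, 0), c(9, 8, 10))
  cran_out <- ellip(c(0, 0, 2), c(6.1, 5.1, 6.6))
  brain <- ellip(c(0, 0, 2), c(5.5, 4.5, 6))
  vert <- (X^2 + (Y + 5.5)^2 <= 3.0^2) & Z >= -10 & Z <= 2 & head
  cord <- (X^2 + (Y + 5.5)^2 <= 0.9^2) & Z >= -10 & Z <= 2 & head
  oss <- ellip(c(5.2, -1, 0), c(1, 1, 1)) | ellip(c(-5.2, -1, 0), c(1, 1, 1))
  tum <- ellip(c(0, -3.5, -1.0), c(2.6, 2.6, 2.6))

  palette <- c("Air", "ICRU Adipose", "Cranium", "Brain", "Spongiosa",
               "Cortical Bone")
  labels <- array(1L, dim = c(n, n, n))
  labels[head] <- 2L
  labels[cran_out & !brain] <- 3L
  labels[brain] <- 4L
  labels[vert] <- 5L
  labels[cord] <- 4L                      # spinal cord shares Brain composition
  labels[oss] <- 6L
  bone <- array(labels %in% c(3L, 5L, 6L), dim = c(n, n, n))
  structures <- list(body = head | vert,
                     tumour = tum & (head | vert),
                     brain = brain & labels == 4L & !cord,
                     spinal_cord = cord,
                     bone = bone)
  .phantom_model(labels, palette, load_materials()[palette], structures,
                 spacing, origin = rep(cx[1], 3))
}
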