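#' Calibrate the dual-energy electron-density estimator
#'
#' Saito-style weighted HU difference: Delta-HU = (1 + alpha) HU_H - alpha
#' HU_L, with rho_e = a Delta-HU / 1000 + b. The weighting alpha is found by
#' a 1-D search maximizing the R-squared of the linear fit of the reference
#' electron densities on Delta-HU/1000.
#'
#' @param hu_low,hu_high Per-material mean HU at the low/high energy
#'   (numeric vectors, same order).
#' @param rhoe_ref Reference relative electron densities, same order.
#' @param alpha_range Search interval for alpha.
#' @return List with `alpha`, `a`, `b`, `r_squared`.
#' @export
calibrate_rhoe <- function(hu_low, hu_high, rhoe_ref,
                           alpha_range = c(-2, 5)) {
  stopifnot(length(hu_low) == length(hu_high),
            length(hu_low) == length(rhoe_ref), length(hu_low) >= 4)
  fit_at <- function(alpha) {
    d <- ((1 + alpha) * hu_high - alpha * hu_low) / 1000
    f <- lm(rhoe_ref ~ d)
    r2 <- 1 - sum(f$residuals^2) / sum((rhoe_ref - mean(rhoe_ref))^2)
    list(r2 = r2, a = unname(coef(f)[2]), b = unname(coef(f)[1]))
  }
  if (max(abs(hu_low - hu_high)) < 1e-9) {
    warning("HU_L = HU_H for all media: alpha is indeterminate")
    f <- fit_at(0)
    return(list(alpha = 0, a = f$a, b = f$b, r_squared = f$r2))
  }
  opt <- optimize(function(a) -fit_at(a)$r2, alpha_range, tol = 1e-6)
  f <- fit_at(opt$minimum)
  if (f$r2 < 0.99)
    warning("poor rho_e calibration: R^2 = ", signif(f$r2, 4))
  list(alpha = opt$minimum, a = f$a, b = f$b, r_squared = f$r2)
}

#' Electron-density map from a dual-energy HU pair
#'
#' @param hu_l,hu_h Co-registered `voxel_volume`s of HU.
#' @param cal A calibration from [calibrate_rhoe()] or [calibrate_dect()].
#' @return `voxel_volume` of relative electron density.
#' @export
rhoe_map <- function(hu_l, hu_h, cal) {
  if (!is.null(cal$rhoe)) cal <- cal$rhoe
  stopifnot(all(dim(hu_l$values) == dim(hu_h$values)))
  d <- ((1 + cal$alpha) * hu_h$values - cal$alpha * hu_l$values) / 1000
  voxel_volume(cal$a * d + cal$b, hu_l$spacing, hu_l$origin, quantity = "rho_e")
}

#' Expected dual-energy attenuation ratio versus effective atomic number
#'
#' For a grid of effective atomic numbers, computes the spectrum-averaged
#' mass attenuation coefficient of a fictitious "pseudo-element" at that Z
#' (log-log interpolation of the elemental tables in Z) for the low and high
#' imaging spectra, and tabulates the low/high ratio, normalized so that the
#' ratio is 1 at the effective atomic number of water. The table must be
#' strictly increasing in Z to be invertible.
#'
#' @param spectrum_low,spectrum_high Imaging spectra.
#' @param z_range Zeff range covered (default 5 to 16, spanning all bundled tissue substitutes).
#' @param dz Grid step.
#' @return List with `z`, `ratio` (normalized), `mu_w_low`, `mu_w_high`
#'   (effective water attenuation, cm^-1) and `z_water`.
#' @export
build_zeff_ratio_table <- function(spectrum_low, spectrum_high,
                                   z_range = c(5, 16), dz = 0.05) {
  z <- seq(z_range[1], z_range[2], by = dz)
  ratio_raw <- vapply(z, function(zz) {
    ml <- .spectrum_weighted(spectrum_low,
                             .pseudo_element_coeff(zz, spectrum_low$energy_bins))
    mh <- .spectrum_weighted(spectrum_high,
                             .pseudo_element_coeff(zz, spectrum_high$energy_bins))
    ml / mh
  }, numeric(1))
  z_water <- effective_atomic_number(water_material())
  r_water <- approx(z, ratio_raw, xout = z_water)$y
  ratio <- ratio_raw / r_water
  if (is.unsorted(ratio, strictly = TRUE))
    stop("attenuation ratio not monotone in Z; spectra too close or invalid")
  list(z = z, ratio = ratio,
       mu_w_low = effective_mu(spectrum_low, water_material()),
       mu_w_high = effective_mu(spectrum_high, water_material()),
       z_water = z_water)
}

#' Effective-atomic-number map from a dual-energy HU pair
#'
#' Per voxel, the measured water-normalized attenuation ratio
#' (HU_L/1000 + 1) / (HU_H/1000 + 1) is inverted through the monotone
#' Z-ratio table. Voxels whose ratio falls outside the table range (or with
#' non-positive attenuation, e.g. deep air voxels) receive no Zeff and are
#' returned in the exclusion mask.
#'
#' @param hu_l,hu_h Co-registered HU volumes.
#' @param cal Calibration holding the ratio table (from
#'   [build_zeff_ratio_table()] or [calibrate_dect()]).
#' @return List with `zeff` (`voxel_volume`) and `excluded` (logical array).
#' @export
zeff_map <- function(hu_l, hu_h, cal) {
  tab <- if (!is.null(cal$zeff_table)) cal$zeff_table else cal
  ml <- hu_l$values / 1000 + 1
  mh <- hu_h$values / 1000 + 1
  bad <- ml <= 0 | mh <= 0
  r <- ml / mh
  r[bad] <- NA_real_
  excluded <- bad | r < min(tab$ratio) | r > max(tab$ratio)
  z <- approx(tab$ratio, tab$z, xout = r)$y
  z[excluded] <- NA_real_
  zv <- array(z, dim = dim(ml))
  zv[excluded] <- 0
  list(zeff = voxel_volume(zv, hu_l$spacing, hu_l$origin, quantity = "z_eff"),
       excluded = array(excluded, dim = dim(ml)))
}

#' Reference (Zeff, rho_e) points for a media list
#'
#' @param media Character vector of material names.
#' @param materials Material database.
#' @return Data frame with `material`, `z_r`, `rho_r` (reference values from
#'   the database).
#' @export
tissue_references <- function(media, materials = load_materials()) {
  data.frame(material = media,
             z_r = vapply(media, function(nm) materials[[nm]]$ref_z_eff, 1),
             rho_r = vapply(media, function(nm) materials[[nm]]$ref_rho_e, 1))
}

#' Mahalanobis tissue assignment in (Zeff, rho_e) space
#'
#' Each voxel's measured pair (Z_C, rho_C) is assigned the reference tissue
#' (Z_R, rho_R) minimizing the Mahalanobis distance under the supplied noise
#' covariance. Exact ties go to the reference with the lower rho_e. Excluded
#' voxels (no Zeff solution) are labelled Air. Mass density is assigned from
#' the rho_e map through the linear rho-rho_e relationship.
#'
#' @param zeff `voxel_volume` of Zeff (or the list returned by [zeff_map()]).
#' @param rhoe `voxel_volume` of rho_e.
#' @param references Data frame from [tissue_references()] (>= 2 rows).
#' @param covariance 2x2 symmetric positive-definite noise covariance of
#'   (Zeff, rho_e); the identity reduces the metric to Euclidean.
#' @param rho_fit List with `slope`, `intercept` (see [fit_rho_vs_rhoe()]).
#' @param excluded Optional logical array of voxels to label Air.
#' @param materials Material database.
#' @return A `material_map`.
#' @export
assign_tissue_mahalanobis <- function(zeff, rhoe, references, covariance,
                                      rho_fit, excluded = NULL,
                                      materials = load_materials()) {
  if (is.list(zeff) && !inherits(zeff, "voxel_volume")) {
    if (is.null(excluded)) excluded <- zeff$excluded
    zeff <- zeff$zeff
  }
  stopifnot(nrow(references) >= 2, all(dim(covariance) == c(2, 2)))
  if (abs(covariance[1, 2] - covariance[2, 1]) > 1e-12)
    stop("covariance must be symmetric")
  si <- tryCatch(solve(covariance), error = function(e)
    stop("singular covariance"))
  if (any(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("covariance must be positive definite")
  ord <- order(references$rho_r)        # tie-break: lower rho_e wins
  refs <- references[ord, ]
  z <- as.vector(zeff$values); r <- as.vector(rhoe$values)
  best_d <- rep(Inf, length(z)); best_i <- rep(1L, length(z))
  for (t in seq_len(nrow(refs))) {
    dz <- z - refs$z_r[t]; dr <- r - refs$rho_r[t]
    d2 <- si[1, 1] * dz^2 + 2 * si[1, 2] * dz * dr + si[2, 2] * dr^2
    upd <- d2 < best_d
    best_d[upd] <- d2[upd]; best_i[upd] <- t
  }
  palette <- refs$material
  labels <- array(best_i, dim = dim(zeff$values))
  if (!is.null(excluded) && any(excluded)) {
    i_air <- which(palette == "Air")
    if (length(i_air) == 0) { palette <- c(palette, "Air"); i_air <- length(palette) }
    labels[excluded] <- i_air[1]
  }
  rho <- pmax(rho_fit$slope * r + rho_fit$intercept, 0.001)
  if ("Air" %in% palette)
    rho[palette[labels] == "Air"] <- materials[["Air"]]$mass_density
  material_map(labels, palette, array(rho, dim = dim(labels)),
               zeff$spacing, zeff$origin, materials)
}

#' End-to-end dual-energy calibration
#'
#' Runs the full DECT calibration on a simulated (or measured) dual-energy
#' pair of the calibration phantom: per-insert ROI statistics at both
#' energies, the Saito alpha/a/b search against the reference electron
#' densities, the Landry Zeff-ratio table for the spectrum pair, the noise
#' covariance of (Zeff, rho_e) estimated over the Solid Water bulk, and the
#' rho-rho_e linear fit over the calibration materials.
#'
#' @param pair List with `low`/`high` HU volumes (see [simulate_dect_pair()]).
#' @param phantom The calibration `phantom_model`.
#' @param spectrum_low,spectrum_high The imaging spectra of the pair.
#' @param erosion_mm ROI erosion (mm).
#' @param materials Material database.
#' @return A calibration object (class `dect_calibration`) with fields
#'   `rhoe`, `zeff_table`, `covariance`, `rho_fit`.
#' @export
calibrate_dect <- function(pair, phantom, spectrum_low, spectrum_high,
                           erosion_mm = 0.3, materials = load_materials()) {
  st_l <- roi_statistics(pair$low, phantom, erosion_mm)
  st_h <- roi_statistics(pair$high, phantom, erosion_mm)
  rhoe_ref <- vapply(st_l$material, function(nm) materials[[nm]]$ref_rho_e, 1)
  cal_rhoe <- calibrate_rhoe(st_l$mean, st_h$mean, rhoe_ref)
  ztab <- build_zeff_ratio_table(spectrum_low, spectrum_high)
  rmap <- rhoe_map(pair$low, pair$high, cal_rhoe)
  zmap <- zeff_map(pair$low, pair$high, ztab)
  bulk <- erode_mask(phantom$structures$bulk, pair$low$spacing, erosion_mm) &
    !zmap$excluded
  s <- cbind(zmap$zeff$values[bulk], rmap$values[bulk])
  covariance <- if (nrow(s) > 10 && all(apply(s, 2, sd) > 0)) stats::cov(s)
                else diag(2)
  cal_mats <- load_materials("calibration")
  structure(list(rhoe = cal_rhoe, zeff_table = ztab, covariance = covariance,
                 rho_fit = fit_rho_vs_rhoe(cal_mats)),
            class = "dect_calibration")
}

#' Dual-energy tissue segmentation
#'
#' Convenience wrapper: decomposes a dual-energy pair into rho_e and Zeff
#' maps with a calibration and assigns tissues from a media list by minimal
#' Mahalanobis distance.
#'
#' @param pair List with `low`/`high` HU volumes.
#' @param cal A `dect_calibration` from [calibrate_dect()].
#' @param media Character vector of media names (e.g.
#'   `scheme_preset("DECT7")`).
#' @param materials Material database.
#' @return A `material_map`.
#' @export
segment_dect <- function(pair, cal, media, materials = load_materials()) {
  rmap <- rhoe_map(pair$low, pair$high, cal)
  zmap <- zeff_map(pair$low, pair$high, cal$zeff_table)
  assign_tissue_mahalanobis(zmap, rmap, tissue_references(media, materials),
                            cal$covariance, cal$rho_fit,
                            materials = materials)
}
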