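#' Define an irradiation beam
#'
#' @param spectrum Treatment spectrum (e.g. `beam_spectrum(225, "treatment")`).
#' @param geometry `"parallel_broad"` (default) or `"divergent"` (point
#'   source at the source-to-isocentre distance).
#' @param gantry_angles Beam directions in degrees (in the axial plane;
#'   opposed beams differ by 180). One transport run per angle, histories
#'   split equally.
#' @param field_size Field width x height at the isocentre plane, in cm
#'   (default `c(3.5, 1)`).
#' @param circular If `TRUE`, a circular aperture of diameter
#'   `field_size[1]` cm is used instead of a rectangle.
#' @param source_to_isocentre Source-to-isocentre distance in mm
#'   (default 303.6; only used for divergent geometry).
#' @param isocentre Isocentre position in mm (grid coordinates); default the
#'   volume centre.
#' @param prescription_gy Planned dose at the prescription target in Gy.
#' @return A `beam_spec` object.
#' @export
beam_spec <- function(spectrum, geometry = c("parallel_broad", "divergent"),
                      gantry_angles = 0, field_size = c(3.5, 1),
                      circular = FALSE, source_to_isocentre = 303.6,
                      isocentre = NULL, prescription_gy = 2) {
  geometry <- match.arg(geometry)
  stopifnot(all(field_size > 0), all(gantry_angles >= 0 & gantry_angles < 360))
  if (length(field_size) == 1) field_size <- rep(field_size, 2)
  structure(list(spectrum = spectrum, geometry = geometry,
                 gantry_angles = gantry_angles, field_size = field_size,
                 circular = circular, sid = source_to_isocentre,
                 isocentre = isocentre, prescription_gy = prescription_gy),
            class = "beam_spec")
}

# engine input tables for a material map: per-palette-entry interaction
# components on a 1 keV grid, plus the Woodcock majorant
.engine_tables <- function(map, e_max) {
  e <- seq(10, max(ceiling(e_max) + 5, 30), by = 1)
  n_m <- length(map$palette)
  pe <- inc <- coh <- matrix(0, length(e), n_m)
  for (j in seq_len(n_m)) {
    cmp <- .material_components(map$materials[[j]], e)
    # 0.1 converts (cm^2/g * g/cm^3) to mm^-1, the engine's length unit
    pe[, j] <- 0.1 * cmp$pe; inc[, j] <- 0.1 * cmp$incoherent
    coh[, j] <- 0.1 * cmp$coherent
  }
  # per-material maximum density actually present in the map
  lab <- map$labels$values
  rho_max <- vapply(seq_len(n_m), function(j) {
    sel <- lab == j
    if (any(sel)) max(map$rho$values[sel]) else 0
  }, numeric(1))
  list(e = e, pe = pe, inc = inc, coh = coh,
       majorant = apply((pe + inc + coh) *
                          rep(rho_max, each = length(e)), 1, max))
}

#' Monte Carlo photon transport on a material map
#'
#' Runs the collision-kerma photon Monte Carlo (see the package vignette for
#' the transport model): Woodcock tracking over the voxel grid,
#' photoelectric absorption deposits locally, Compton deposits the electron
#' share locally and transports the scattered photon; photons below 10 keV
#' deposit locally and terminate; no secondary electron transport. Dose is
#' scored per voxel as energy/mass; air voxels are not scored. Per-voxel
#' statistical uncertainty is estimated from independent batches. Runs are
#' bit-reproducible for a fixed seed.
#'
#' @param map A `material_map`.
#' @param beam A [beam_spec()].
#' @param histories Total number of photon histories (>= 1e4), split over
#'   gantry angles and batches.
#' @param seed Integer master seed.
#' @param n_batch Number of uncertainty batches (>= 10).
#' @param primary_only If `TRUE`, photons deposit all energy at their first
#'   interaction and terminate (analytic-benchmark mode).
#' @param rayleigh If `TRUE`, coherent scattering redirects photons
#'   (off by default).
#' @param pcut Photon transport cutoff in keV (default 10).
#' @param majorant Optional Woodcock majorant override (an object returned in
#'   the `majorant_info` field of a previous run, or built with
#'   [shared_majorant()]). Supplying the same majorant to two runs on
#'   different material maps makes them use common random numbers
#'   (correlated sampling): identical voxels see identical histories, so
#'   dose-difference maps carry far less Monte Carlo noise. Must dominate
#'   the attenuation of every voxel of the map.
#' @return A `dose_grid`: `dose` (`voxel_volume`, Gy per history),
#'   `rel_uncertainty` (fractional, NA where no dose), `histories`, `seed`,
#'   `energy_entering_kev`, `energy_deposited_kev`.
#' @export
transport <- function(map, beam, histories, seed = 1L, n_batch = 10L,
                      primary_only = FALSE, rayleigh = FALSE, pcut = 10,
                      majorant = NULL) {
  stopifnot(inherits(map, "material_map"), inherits(beam, "beam_spec"),
            histories >= 1e4, n_batch >= 2)
  lab <- map$labels
  d <- dim(lab$values)
  iso <- beam$isocentre
  if (is.null(iso)) iso <- lab$origin + (d - 1) / 2 * lab$spacing
  tabs <- .engine_tables(map, max(beam$spectrum$energy_bins))
  if (!is.null(majorant)) {
    if (length(majorant$majorant) != length(tabs$majorant) ||
        any(majorant$e != tabs$e))
      stop("majorant energy grid does not match this beam's grid")
    if (any(majorant$majorant < tabs$majorant - 1e-12))
      stop("supplied majorant does not dominate this material map")
    tabs$majorant <- majorant$majorant
  }
  cdf <- cumsum(beam$spectrum$fluence); cdf <- cdf / cdf[length(cdf)]
  n_ang <- length(beam$gantry_angles)
  hist_per <- floor(histories / n_ang)
  tot <- tot2 <- 0; e_in <- e_dep <- 0; nb_tot <- 0L; hist_tot <- 0
  for (a in seq_len(n_ang)) {
    bl <- list(geometry_code = if (beam$geometry == "parallel_broad") 0L else 1L,
               angle_rad = beam$gantry_angles[a] * pi / 180,
               sid_mm = beam$sid, field_w_mm = beam$field_size[1] * 10,
               field_h_mm = beam$field_size[2] * 10,
               circular = beam$circular, isocentre_mm = as.numeric(iso))
    res <- cpp_transport(as.integer(lab$values), as.integer(d),
                         as.numeric(lab$spacing), as.numeric(lab$origin),
                         as.numeric(map$rho$values),
                         as.logical(map$score_mask),
                         tabs$pe, tabs$inc, tabs$coh, tabs$e[1],
                         tabs$majorant,
                         beam$spectrum$energy_bins, cdf, bl,
                         hist_per, as.integer(n_batch),
                         as.numeric(seed) + (a - 1) * 7919, pcut,
                         primary_only, rayleigh)
    tot <- tot + res$edep_kev; tot2 <- tot2 + res$batch_sumsq
    e_in <- e_in + res$e_entering_kev; e_dep <- e_dep + res$e_deposited_kev
    nb_tot <- nb_tot + res$n_batch; hist_tot <- hist_tot + res$histories
  }
  # per-voxel fractional uncertainty from batch spread (batches pooled over
  # angles; per-angle contributions are independent)
  nb <- nb_tot
  s2 <- pmax(tot2 - tot^2 / nb, 0) / (nb - 1)
  rel <- ifelse(tot > 0, sqrt(nb * s2) / tot, NA_real_)
  mass_g <- map$rho$values * prod(lab$spacing) / 1000  # mm^3 -> cm^3
  dose <- array(0, d)
  nz <- mass_g > 0 & map$score_mask
  dose[nz] <- tot[nz] * 1.602176634e-16 / (mass_g[nz] * 1e-3) / hist_tot
  structure(list(
    dose = voxel_volume(dose, lab$spacing, lab$origin, quantity = "dose"),
    rel_uncertainty = array(rel, d), histories = hist_tot, seed = seed,
    energy_entering_kev = e_in, energy_deposited_kev = e_dep,
    majorant_info = list(e = tabs$e, majorant = tabs$majorant)),
    class = "dose_grid")
}

#' Common Woodcock majorant for correlated transport runs
#'
#' Builds a majorant dominating several material maps (for the same beam
#' spectrum), so that [transport()] runs on each map share random-number
#' streams history-by-history and their dose differences are nearly free of
#' common Monte Carlo noise.
#'
#' @param maps List of `material_map`s on the same grid.
#' @param spectrum The beam spectrum all runs will use.
#' @return A majorant object for the `majorant` argument of [transport()].
#' @export
shared_majorant <- function(maps, spectrum) {
  tabs <- lapply(maps, .engine_tables, e_max = max(spectrum$energy_bins))
  list(e = tabs[[1]]$e,
       majorant = Reduce(pmax, lapply(tabs, `[[`, "majorant")))
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid>", paste(dim(x$dose$values), collapse = "x"), "voxels,",
      format(x$histories, big.mark = ","), "histories\n")
  m <- x$dose$values > 0
  cat("  max dose:", signif(max(x$dose$values), 4), "Gy; median rel. unc.:",
      signif(stats::median(x$rel_uncertainty[m], na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Scale a dose grid to a prescription
#'
#' Global scaling so that the dose at a target point (or the mean over a
#' target mask) equals the prescription.
#'
#' @param dose A `dose_grid`.
#' @param target A point in mm (length-3 numeric) or a logical mask array;
#'   `NULL` uses the volume centre.
#' @param value Prescription in Gy (default 2).
#' @return The rescaled `dose_grid` (relative uncertainties unchanged).
#' @export
normalize_to_prescription <- function(dose, target = NULL, value = 2.0) {
  v <- dose$dose
  if (is.null(target))
    target <- v$origin + (dim(v$values) - 1) / 2 * v$spacing
  if (is.logical(target)) {
    d0 <- mean(v$values[target])
  } else {
    idx <- round((target - v$origin) / v$spacing) + 1
    idx <- pmin(pmax(idx, 1), dim(v$values))
    d0 <- v$values[idx[1], idx[2], idx[3]]
  }
  if (!is.finite(d0) || d0 <= 0) stop("zero dose at the prescription target")
  dose$dose$values <- v$values * (value / d0)
  dose$prescription_gy <- value
  dose
}

#' Analytic misassignment dose-ratio oracle
#'
#' First-order prediction of the dose change when medium `scored` is scored
#' in a voxel whose true medium is `truth`: the ratio of the
#' spectrum-averaged (energy-fluence-weighted) mass energy-absorption
#' coefficients, muen/rho(scored) / muen/rho(truth). Under the kerma
#' approximation the local dose is proportional to this coefficient, so the
#' ratio predicts the misassignment dose error before any transport effects.
#'
#' @param truth,scored [material()] objects.
#' @param spectrum Treatment spectrum.
#' @return Dimensionless dose ratio.
#' @export
insert_dose_ratio_oracle <- function(truth, scored, spectrum) {
  mu_t <- mass_attenuation(truth, spectrum$energy_bins, "energy_absorption")
  mu_s <- mass_attenuation(scored, spectrum$energy_bins, "energy_absorption")
  .spectrum_weighted(spectrum, mu_s) / .spectrum_weighted(spectrum, mu_t)
}
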