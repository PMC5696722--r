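#' X-ray spectra
#'
#' A spectrum is a binned photon fluence versus energy for a given tube
#' voltage and filtration: uniform 1 keV bins from 10 keV up to the kVp,
#' fluence normalized to unit sum. Spectra can be generated with a simple
#' filtered-bremsstrahlung model ([generate_spectrum()]) or loaded from a
#' two-column text file ([load_spectrum()]) when externally computed spectra
#' are preferred.
#'
#' @name spectra
NULL

.spectrum <- function(kvp, energy, fluence, filtration = list()) {
  if (any(fluence < 0)) stop("negative fluence")
  if (any(energy > kvp + 1e-9 & fluence > 0)) stop("fluence above the kVp endpoint")
  if (sum(fluence) <= 0) stop("all-zero spectrum")
  structure(list(kvp = kvp, energy_bins = energy,
                 fluence = fluence / sum(fluence), filtration = filtration),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum>", x$kvp, "kVp,", length(x$energy_bins), "bins, mean energy",
      round(spectrum_mean_energy(x), 2), "keV\n")
  invisible(x)
}

#' Fluence-weighted mean energy of a spectrum
#' @param spectrum A spectrum.
#' @return Mean energy in keV.
#' @export
spectrum_mean_energy <- function(spectrum) {
  sum(spectrum$energy_bins * spectrum$fluence)
}

# densities of filter materials, g/cm^3
.filter_density <- c(Al = 2.699, Cu = 8.960, Be = 1.848)

#' Generate a filtered bremsstrahlung spectrum
#'
#' Kramers-form bremsstrahlung (fluence proportional to (E_max - E)/E)
#' attenuated through the listed filters; tungsten K-characteristic lines are
#' added for tube voltages above the K-edge (69.5 keV) at a fixed relative
#' intensity. This deliberately simple model captures the endpoint, beam
#' hardening with filtration and the qualitative shape; externally computed
#' spectra can be substituted via [load_spectrum()].
#'
#' @param kvp Tube voltage in kV (30-225).
#' @param filtration List of `list(material=, thickness_mm=)` entries;
#'   filter materials: `"Al"`, `"Cu"`, `"Be"`.
#' @param anode_angle Anode angle in degrees (kept for interface completeness;
#'   the Kramers model has no angular dependence).
#' @return A `spectrum` with 1 keV bins from 10 keV to the kVp, unit total
#'   fluence.
#' @examples
#' s <- generate_spectrum(90, filtration = list(list(material = "Al", thickness_mm = 2)))
#' spectrum_mean_energy(s)
#' @export
generate_spectrum <- function(kvp, filtration = list(), anode_angle = 20) {
  stopifnot(kvp >= 30, kvp <= 225)
  e <- seq(10, kvp, by = 1)
  phi <- pmax(kvp - e, 0) / e
  for (f in filtration) {
    mat <- f$material
    if (!mat %in% names(.filter_density))
      stop("unknown filter material '", mat, "'")
    mu <- element_mass_coeff(mat, e) * .filter_density[[mat]]  # cm^-1
    phi <- phi * exp(-mu * f$thickness_mm / 10)
  }
  # tungsten K lines (Kalpha2, Kalpha1, Kbeta1) with fixed relative intensity
  if (kvp > 69.5) {
    kl <- c(`58` = 0.30, `59` = 0.55, `67` = 0.15)
    scale <- 0.6 * max(phi)
    for (le in names(kl)) {
      i <- which(e == as.numeric(le))
      if (length(i)) phi[i] <- phi[i] + scale * kl[[le]]
    }
  }
  .spectrum(kvp, e, phi, filtration)
}

#' Load a spectrum from a text file
#'
#' Expects header lines starting with `#`, then rows of
#' `energy_keV fluence`. Energies must be strictly increasing and fluence
#' non-negative; the fluence is renormalized to unit sum.
#'
#' @param path File path.
#' @return A `spectrum`.
#' @export
load_spectrum <- function(path) {
  d <- read.table(path, comment.char = "#")
  e <- d[[1]]; phi <- d[[2]]
  if (is.unsorted(e, strictly = TRUE)) stop("energies must be strictly increasing")
  if (any(phi < 0)) stop("negative fluence")
  .spectrum(max(e), e, phi)
}

#' Save a spectrum to the text format read by [load_spectrum()]
#' @param spectrum A spectrum.
#' @param path Output file path.
#' @export
save_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  writeLines(sprintf("# kvseg spectrum: %g kVp", spectrum$kvp), con)
  write.table(data.frame(spectrum$energy_bins, signif(spectrum$fluence, 8)),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Imaging and treatment beam presets
#'
#' Imaging beams: 50 and 90 kVp with 0.8 mm Be exit window plus 2.0 mm Al.
#' Treatment beams: 100, 160 and 225 kVp with 0.8 mm Be plus 0.32 mm Cu.
#'
#' @param kvp Tube voltage.
#' @param mode `"imaging"` or `"treatment"`.
#' @return A `spectrum`.
#' @export
beam_spectrum <- function(kvp, mode = c("imaging", "treatment")) {
  mode <- match.arg(mode)
  filt <- list(list(material = "Be", thickness_mm = 0.8))
  filt[[2]] <- if (mode == "imaging")
    list(material = "Al", thickness_mm = 2.0)
  else list(material = "Cu", thickness_mm = 0.32)
  generate_spectrum(kvp, filtration = filt)
}

#' Spectrum-averaged linear attenuation coefficient
#'
#' Energy-fluence-weighted effective linear attenuation coefficient of a
#' material, the quantity that defines simulated Hounsfield Units for an
#' energy-integrating detector:
#' mu_eff = rho * sum(phi_b E_b (mu/rho)(E_b)) / sum(phi_b E_b).
#'
#' @param spectrum A spectrum.
#' @param material A [material()].
#' @param weighting `"energy_fluence"` (default, energy-integrating detector)
#'   or `"fluence"` (photon-counting).
#' @return Effective mu in cm^-1.
#' @export
effective_mu <- function(spectrum, material,
                         weighting = c("energy_fluence", "fluence")) {
  weighting <- match.arg(weighting)
  w <- spectrum$fluence
  if (weighting == "energy_fluence") w <- w * spectrum$energy_bins
  mu_rho <- mass_attenuation(material, spectrum$energy_bins)
  material$mass_density * sum(w * mu_rho) / sum(w)
}

# spectrum-averaged mass coefficient (cm^2/g) of an arbitrary coefficient
# vector, energy-fluence weighted; internal helper shared by the DECT ratio
# table and the dose-ratio oracle
.spectrum_weighted <- function(spectrum, coeff,
                               weighting = "energy_fluence") {
  w <- spectrum$fluence
  if (weighting == "energy_fluence") w <- w * spectrum$energy_bins
  sum(w * coeff) / sum(w)
}
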