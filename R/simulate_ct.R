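#' Simulate a CT scan of a phantom
#'
#' Image-domain CT simulation: each voxel receives the Hounsfield Unit of its
#' ground-truth material, HU = 1000 (mu/mu_w - 1), where mu is the
#' spectrum-averaged linear attenuation coefficient ([effective_mu()]) and
#' mu_w that of liquid water. The noiseless map is blurred with an isotropic
#' Gaussian point-spread function (a partial-volume surrogate) and then
#' degraded with additive Gaussian noise. Beam hardening, scatter and
#' reconstruction artefacts are deliberately not modelled.
#'
#' @param phantom A [build_cylinder_phantom()] / [build_rodent_head_phantom()]
#'   model.
#' @param spectrum Imaging spectrum (e.g. `beam_spectrum(50, "imaging")`).
#' @param noise_sigma Noise standard deviation in HU: a single number, or a
#'   named vector of per-material sigmas (materials absent from the vector
#'   get 0).
#' @param psf_fwhm Gaussian PSF full width at half maximum in mm
#'   (default 0.2, about two voxels at the native 0.1034 mm spacing).
#' @param seed Integer seed; the simulation is deterministic for a fixed seed.
#' @return A `voxel_volume` of HU.
#' @export
simulate_ct <- function(phantom, spectrum, noise_sigma = 0, psf_fwhm = 0.2,
                        seed = 1L) {
  lab <- phantom$labels
  mu_w <- effective_mu(spectrum, water_material())
  mu_m <- vapply(phantom$palette, function(nm)
    effective_mu(spectrum, phantom$materials[[nm]]), numeric(1))
  hu_m <- 1000 * (mu_m / mu_w - 1)
  hu <- array(hu_m[lab$values], dim = dim(lab$values))
  hu <- .gaussian_blur3d(hu, lab$spacing, psf_fwhm)
  if (is.null(names(noise_sigma))) {
    sig <- array(noise_sigma[1], dim = dim(hu))
  } else {
    # per-palette-entry sigma by material name (palettes may repeat names)
    sig_m <- unname(noise_sigma[phantom$palette])
    sig_m[is.na(sig_m)] <- 0
    sig <- array(sig_m[lab$values], dim = dim(hu))
  }
  if (any(sig > 0)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    hu <- hu + array(rnorm(length(hu), sd = 1), dim = dim(hu)) * sig
  }
  voxel_volume(hu, lab$spacing, lab$origin, quantity = "HU")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a co-registered dual-energy CT pair
#'
#' Two [simulate_ct()] runs on the same geometry with independent noise
#' realizations (seeds `seed` and `seed + 1`). No resampling occurs anywhere,
#' so the pair is registered exactly.
#'
#' @param phantom Phantom model.
#' @param spectrum_low,spectrum_high Low/high energy imaging spectra.
#' @param noise_sigma_low,noise_sigma_high Noise levels for each scan (see
#'   [simulate_ct()]).
#' @param psf_fwhm PSF FWHM in mm.
#' @param seed Integer seed.
#' @return List with elements `low` and `high` (`voxel_volume`s of HU).
#' @export
simulate_dect_pair <- function(phantom, spectrum_low, spectrum_high,
                               noise_sigma_low = 0, noise_sigma_high = 0,
                               psf_fwhm = 0.2, seed = 1L) {
  if (isTRUE(all.equal(spectrum_low, spectrum_high)))
    warning("identical spectra: the dual-energy decomposition is degenerate")
  list(low = simulate_ct(phantom, spectrum_low, noise_sigma_low, psf_fwhm, seed),
       high = simulate_ct(phantom, spectrum_high, noise_sigma_high, psf_fwhm,
                          seed + 1L))
}
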