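# Shared fixtures, built once per test session. Phantoms use 0.2 mm voxels
# and short (2 mm) cylinder stacks: the cylindrical geometry is
# translation-invariant along the axis, so short stacks probe the same
# physics at a fraction of the cost.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- expr
  .fixtures[[name]]
}

spec50 <- function() fx("s50", beam_spectrum(50, "imaging"))
spec90 <- function() fx("s90", beam_spectrum(90, "imaging"))

cal_phantom <- function()
  fx("cal_ph", build_cylinder_phantom("calibration", spacing = 0.2, length_mm = 2))
val_phantom <- function()
  fx("val_ph", build_cylinder_phantom("validation", spacing = 0.2, length_mm = 2))

# noiseless, blur-free pairs for closure checks
cal_pair_clean <- function()
  fx("cal_pair_clean",
     simulate_dect_pair(cal_phantom(), spec50(), spec90(), psf_fwhm = 0))
val_pair_clean <- function()
  fx("val_pair_clean",
     simulate_dect_pair(val_phantom(), spec50(), spec90(), psf_fwhm = 0))
dect_cal_clean <- function()
  fx("dect_cal_clean",
     calibrate_dect(cal_pair_clean(), cal_phantom(), spec50(), spec90()))

# pairs with the measured per-insert noise levels injected
cal_pair_noisy <- function()
  fx("cal_pair_noisy",
     simulate_dect_pair(cal_phantom(), spec50(), spec90(),
                        noise_sigma_low = phantom_noise_levels("calibration", 50),
                        noise_sigma_high = phantom_noise_levels("calibration", 90),
                        seed = 10))
val_pair_noisy <- function()
  fx("val_pair_noisy",
     simulate_dect_pair(val_phantom(), spec50(), spec90(),
                        noise_sigma_low = phantom_noise_levels("validation", 50),
                        noise_sigma_high = phantom_noise_levels("validation", 90),
                        seed = 20))
dect_cal_noisy <- function()
  fx("dect_cal_noisy",
     calibrate_dect(cal_pair_noisy(), cal_phantom(), spec50(), spec90()))

# eroded interior of the validation phantom: bulk plus all inserts except
# Teflon (not used in the study), 0.4 mm margin
val_interior <- function() fx("val_interior", {
  st <- val_phantom()$structures
  interior <- erode_mask(st$bulk, 0.2, 0.4)
  for (k in setdiff(1:12, 2))
    interior <- interior | erode_mask(st[[paste0("insert_", k)]], 0.2, 0.4)
  interior
})

# homogeneous water cube, 41 mm at 1 mm voxels (odd size: the volume centre
# falls exactly on a voxel centre)
water_slab <- function() fx("water_slab", {
  n <- 41L
  material_map(array(1L, c(n, n, n)), "Water", array(1.0, c(n, n, n)),
               spacing = 1, origin = rep(-(n - 1) / 2, 3))
})

mono_spectrum <- function(kev = 60) {
  tf <- tempfile(fileext = ".txt")
  writeLines(sprintf("%g 1.0", kev), tf)
  load_spectrum(tf)
}
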