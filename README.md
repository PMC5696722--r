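# kvseg

Tissue segmentation from single- and dual-energy CT, and what it does to
kilovolt photon dose calculations in pre-clinical (small-animal)
radiotherapy.

Small-animal irradiators image and treat with the same kV x-ray tube. At
these energies the photoelectric cross-section scales roughly with
Z_eff^3-4, so absorbed dose depends on *which tissue* occupies a voxel, not
just on its density — a wrong material label can shift local dose by tens
of percent. `kvseg` builds the whole chain needed to study this
quantitatively, with known ground truth:

* **materials** — compositions → relative electron density
  ρe = ρ·Σ(wᵢZᵢ/Aᵢ) / [ρw·Σ(wᵢZᵢ/Aᵢ)]w, effective atomic number
  Z_eff = (Σ fᵢZᵢⁿ)^(1/n) with n = 3.31, and mass attenuation /
  energy-absorption coefficients by the mixture rule (bundled 10–250 keV
  elemental tables);
* **spectra** — filtered-bremsstrahlung imaging (50/90 kVp + 2 mm Al) and
  treatment (100/160/225 kVp + 0.32 mm Cu) beams, or file-loaded spectra;
* **synthetic CT** — digital twins of a 3 cm calibration/validation
  cylinder phantom (12 tissue-substitute inserts) and an idealized
  rodent head (six ICRU-44 tissues), imaged as
  HU = 1000(μ/μw − 1) plus Gaussian blur and measured per-insert noise;
* **SECT** — piecewise bi-linear HU→ρ calibration pinned at water, plus
  threshold segmentation (3/4/7-media presets);
* **DECT** — electron density from a weighted HU difference
  ΔHU = (1+α)·HU_H − α·HU_L, Z_eff by inverting a water-normalized
  attenuation-ratio table, Mahalanobis tissue assignment in (Z_eff, ρe)
  space (7/8/9-media presets);
* **dose** — a photon-only voxel Monte Carlo under the collision-kerma
  approximation (Woodcock tracking, Klein–Nishina Compton, 10 keV photon
  cutoff, no secondary electrons), with correlated-sampling support for
  low-noise dose *difference* studies;
* **compare** — ΔD maps, per-ROI statistics, misassignment fractions,
  dose-error histograms and DVHs (D95/D5/D1 as interpolated order
  statistics).

## Worked example

Simulate noisy dual-energy scans of both phantoms, calibrate, segment with
a three-media SECT scheme and a seven-media DECT scheme, and compare a
225 kVp dose calculation against the ground-truth map:

```r
library(kvseg)
s50 <- beam_spectrum(50, "imaging");  s90 <- beam_spectrum(90, "imaging")

cal <- build_cylinder_phantom("calibration", spacing = 0.2, length_mm = 2)
val <- build_cylinder_phantom("validation",  spacing = 0.2, length_mm = 2)
cal_pair <- simulate_dect_pair(cal, s50, s90,
  noise_sigma_low  = phantom_noise_levels("calibration", 50),
  noise_sigma_high = phantom_noise_levels("calibration", 90), seed = 10)
val_pair <- simulate_dect_pair(val, s50, s90,
  noise_sigma_low  = phantom_noise_levels("validation", 50),
  noise_sigma_high = phantom_noise_levels("validation", 90), seed = 20)

dcal <- calibrate_dect(cal_pair, cal, s50, s90)
dcal$rhoe
#> alpha 2.003  a 1.009  b 1.0061  R2 0.99996

m_dect <- segment_dect(val_pair, dcal, scheme_preset("DECT7"))
ref <- reference_material_map(val)
interior <- erode_mask(val$structures$bulk, 0.2, 0.4)
for (k in setdiff(1:12, 2))
  interior <- interior | erode_mask(val$structures[[paste0("insert_", k)]], 0.2, 0.4)
misassignment_fraction(m_dect, ref, interior)$fraction
#> 0.191
```

The seven-media dual-energy map disagrees with the ground truth on 19% of
interior voxels at these noise levels (the disagreement is dominated by the
Water and Muscle inserts, which the scheme deliberately absorbs into Solid
Water, and by soft-tissue flips in the bulk). The same comparison for a
seven-media *single*-energy segmentation of the 90 kVp scan gives 42% —
threshold segmentation destabilizes once media lie within two noise
standard deviations of each other, while a three-media SECT map stays at
7% by not attempting the distinction at all.

Dose impact, with correlated Monte Carlo runs so the difference map is
nearly free of statistical noise:

```r
spec <- beam_spectrum(225, "treatment")
beam <- beam_spec(spec, gantry_angles = 0, field_size = c(3.5, 0.2))
ref_c <- downsample_volume(ref); dect_c <- downsample_volume(m_dect)
mj <- shared_majorant(list(ref_c, dect_c), spec)
d_ref  <- transport(ref_c,  beam, histories = 2e6, seed = 5, majorant = mj)
d_dect <- transport(dect_c, beam, histories = 2e6, seed = 5, majorant = mj)
dd <- dose_difference_map(d_dect, d_ref)
roi_dose_stats(dd, list(lucite = downsample_volume(val$structures$insert_3),
                        muscle = downsample_volume(val$structures$insert_8)),
               erosion_mm = 0.4)
#>      roi  mean   sd n_voxels
#> 1 lucite -0.39 7.49      114
#> 2 muscle  2.36 7.78      108
```

Lucite, a DECT7 medium, is reproduced to well under a percent; Muscle,
scored as Solid Water, picks up a systematic +2.4% at 225 kVp (more at
100 kVp). The analytic first-order prediction of such misassignment errors
is the spectrum-weighted μen/ρ ratio:

```r
db <- load_materials()
insert_dose_ratio_oracle(db$Lucite, db$`Solid Water`, spec)
#> 1.15   # scoring Lucite as Solid Water overestimates its dose by ~15%
```

The rodent-head workflow (multi-bone vs cortical-only segmentation,
parallel-opposed beams, DVHs with `compute_dvh()` and
`count_dose_plateaus()`) is exercised in `tests/testthat/test-acceptance.R`
and described in the methods vignette (`vignettes/kvseg-methods.Rmd`).

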