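---
title: "Methods: CT tissue segmentation and kilovolt dose impact with kvseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT tissue segmentation and kilovolt dose impact with kvseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Small-animal irradiators treat with kilovolt (kV) photons, where the
photoelectric effect makes absorbed dose strongly dependent on the effective
atomic number (Zeff) of the tissue, not only on its density. Monte Carlo dose
engines therefore need a *material map*: a voxelwise assignment of tissue
type and mass density. That map comes from CT, and two pathways compete:

* **SECT** (single-energy CT): a piecewise-linear HU-to-density calibration
  plus user-chosen HU thresholds between media;
* **DECT** (dual-energy CT): two scans at different tube voltages (here
  50 and 90 kVp) decomposed into relative electron density (rho_e) and
  Zeff, with tissues assigned by nearest reference in (Zeff, rho_e) space.

kvseg implements both pathways end to end on fully specified digital
phantoms, runs a photon-only Monte Carlo dose engine on the resulting maps,
and quantifies how segmentation errors propagate into dose: difference maps,
misassignment fractions, error histograms and dose-volume histograms (DVHs).
Because the phantoms are synthetic, the ground truth is known exactly and
every segmentation artefact can be traced.

## Radiological quantities

A material is a mass density plus elemental mass fractions. From these kvseg
derives:

* electrons per gram, `sum(w_i * Z_i / A_i)`;
* relative electron density, referenced to liquid water at exactly
  1.000 g/cm^3;
* effective atomic number as the electron-fraction power mean
  `(sum f_i Z_i^n)^(1/n)` with exponent `n = 3.31`. This exponent
  reproduces the manufacturer/ICRU reference Zeff of 18 of the 19 bundled
  phantom plastics to better than 0.3% (the adipose substitute AP6 is the
  outlier at ~0.8%; its printed reference value is not reachable from its
  printed composition under any power-mean exponent near this range);
* mass attenuation and mass energy-absorption coefficients by the mixture
  rule over bundled elemental tables (10-250 keV, log-log interpolated).

The elemental tables are generated by an in-repo parameterized model
(`tools/make-element-tables.R`): exact Klein-Nishina incoherent scattering
on free electrons, a power-law photoelectric term `C Z^4.166 / A / E^3.05`
and a power-law coherent term anchored to standard oxygen values. All
K-edges of the covered elements (H through Cu) lie below 10 keV, so the
grids are smooth. Accuracy is a few percent against standard tabulations;
since every pipeline quantity is either relative to water (HU, rho_e,
Zeff ratios) or a ratio between media (dose errors), this parameterization
is internally consistent by construction and adequate for the package's
closure- and trend-type claims. It is not a replacement for reference data
in absolute dosimetry.

## Spectra

Imaging (50/90 kVp, 0.8 mm Be + 2.0 mm Al) and treatment
(100/160/225 kVp, 0.8 mm Be + 0.32 mm Cu) spectra come from a deliberately
simple model: Kramers bremsstrahlung (fluence proportional to
`(E_max - E)/E`) in 1 keV bins from 10 keV, filtered through the listed
attenuators, with fixed-intensity tungsten K lines added above 69.5 kV.
`load_spectrum()` is the fidelity escape hatch for externally computed
spectra. Anode self-filtration is not modelled, so the imaging spectra are
somewhat softer than a real tube's; consequently synthetic HU of high-Zeff
media are larger than scanner-measured values (e.g. the densest bone
substitute lands near +5200 HU at 50 kVp where the scanner reports +3723).
All package claims are therefore formulated as closures (simulate,
decompose, recover) or trends, never as absolute HU comparisons, and the
HU anchors (water 0, air about -999) hold exactly by construction.

Simulated HU uses the energy-fluence-weighted effective attenuation
coefficient (energy-integrating detector assumption);
`effective_mu(..., weighting = "fluence")` switches to photon counting.

## Synthetic CT

`build_cylinder_phantom()` builds the 3 cm Solid Water cylinder with twelve
3.5 mm inserts on a 10.5 mm ring (numbered clockwise from 12 o'clock;
no insert coordinates are published, so the ring layout is this package's
convention). `simulate_ct()` assigns each voxel the HU of its true
material, applies a Gaussian point-spread blur (default FWHM 0.2 mm, about
two native 0.1034 mm voxels) as a partial-volume surrogate, then adds
Gaussian noise. Noise can be a scalar or per-material sigmas;
`phantom_noise_levels()` returns the per-insert standard deviations measured
on the physical phantoms at 50 and 90 kVp. Teflon, absent from the measured
table (it was not used in the reference analysis), inherits the bone
sigma; the Solid Water bulk uses the calibration-phantom Solid Water sigma.
Beam hardening, scatter, ring artefacts and reconstruction are out of
scope: noise and blur are the modelled degradations, so synthetic scans are
cleaner than real ones and segmentation results on them are upper bounds on
real-data performance.

`build_rodent_head_phantom()` is an idealized ellipsoidal head made of the
six ICRU Report 44 tissues (adipose shell, cranium shell around a brain,
a spongiosa vertebra enclosing a brain-composition spinal-cord canal, two
cortical-bone ossicles, air outside), with a fictitious spherical tumour
mask overlapping both brain and cord. It reproduces the *topology* of the
treatment problem (an organ at risk enclosed by bone, a tumour straddling
two structures, mostly-spongiosa skeleton), not real anatomy, and all
mouse-case conclusions are trend-based.

Dual-energy pairs share geometry exactly (no resampling anywhere), with
independent noise draws from seeds `seed` and `seed + 1`.

## SECT pathway

ROI statistics are taken over ground-truth regions eroded by 0.3 mm to
exclude the blur band. The HU-density calibration is piecewise bi-linear,
pinned at the water point (0 HU, 1.000 g/cm^3): one constrained
least-squares segment over media with mean HU in (-900, 0], one over
media with HU >= 0. Air is represented by an explicit clamp to its density
at and below -1000 HU rather than by the fit - its leverage would drag the
soft-tissue segment ~20% off. Even so, a bi-linear curve cannot beat about
10% density error for media whose Zeff departs from the fitted line (HU
confounds density with atomic number); that limitation is intrinsic to the
SECT method and is one of the effects the package quantifies.

Thresholds between media default to midpoints of their mean HU (the manual
"visual inspection" step automated); explicit thresholds are accepted, and
the cortical-only rodent scheme uses one placed just above soft tissue so
that *all* bone maps to the single bone medium, as in common pre-clinical
practice.

## DECT pathway

* **rho_e**: weighted HU difference
  `DHU = (1 + alpha) HU_H - alpha HU_L`, `rho_e = a DHU/1000 + b`, with
  `alpha` found by a 1-D search maximizing the R^2 of the linear fit
  against the reference electron densities of the calibration inserts.
* **Zeff**: the measured water-normalized attenuation ratio
  `(HU_L/1000 + 1)/(HU_H/1000 + 1)` is inverted through a monotone table of
  pseudo-element ratios. The table spans Zeff 5 to 16 - wide enough to
  include paraffin (5.48) and the densest bone substitute (13.64) - using
  log-log interpolation between neighbouring elements at non-integer Z, and
  is normalized to 1 at the Zeff of water so that water inverts exactly.
  Voxels whose ratio falls outside the table (chiefly sharp air/solid
  transitions) are excluded, mirrored on the reference analysis, and are
  labelled Air downstream.
* **assignment**: minimal Mahalanobis distance in (Zeff, rho_e) between the
  voxel and the scheme's reference tissues. The noise covariance is
  estimated from the (Zeff, rho_e) samples over the calibration phantom's
  Solid Water bulk; with noiseless input it degenerates and the identity is
  used (Euclidean distance). Exact ties go to the lower reference rho_e -
  deterministic and documented. Mass density is assigned through the linear
  rho-rho_e fit over the twelve calibration materials (slope 1.073,
  intercept -0.037 here; R^2 0.997).

On noiseless synthetic pairs the decomposition closes to better than 1% in
rho_e and 2% in Zeff for all validation media except Teflon
(fluorine-dominated, rho_e 1.86, beyond the calibration range; it is also
excluded from the reference analysis), and the seven-media scheme labels
every interior voxel of its media correctly.

## Dose engine

`transport()` is a photon-only voxel Monte Carlo under the collision-kerma
approximation: no secondary electrons are transported, so energy
transferred to electrons is deposited where it is released. This matches
the transport configuration it emulates (electron cutoff above the maximum
beam energy) and is accurate while electron ranges are sub-voxel, i.e. for
beams up to 225 kVp at 0.1-0.6 mm voxels.

* Free flight by Woodcock (delta) tracking with a per-energy-bin majorant
  over the volume; grid-agnostic and exact.
* Photoelectric events absorb locally; Compton scattering samples the
  Klein-Nishina distribution on free electrons (no binding, no Doppler
  broadening), deposits the electron share locally and transports the
  scattered photon; photons below 10 keV (the photon cutoff) deposit
  locally and terminate.
* Coherent (Rayleigh) scattering is off by default; note the convention:
  with Rayleigh off, coherent events are excluded from the transported
  cross-section entirely, so the effective attenuation is
  photoelectric + incoherent (about 5% below the full mu in water at
  60 keV). Analytic Beer-Lambert benchmarks therefore run with
  `rayleigh = TRUE`.
* No dose is scored in air.
* Beams: parallel broad fields or a divergent point source at 303.6 mm,
  rectangular or circular apertures defined in the isocentre plane, any set
  of gantry angles in the axial plane (histories split equally).
* Uncertainty: per-voxel fractional sigma from >= 10 independent batches;
  it scales as histories^-0.5.
* Reproducibility: a self-contained xoshiro256++ generator seeded per
  (seed, batch, history) makes runs bit-identical for a fixed seed and
  enables *correlated sampling*: two runs on different material maps that
  share a dominating majorant (`shared_majorant()`) consume identical
  random-number streams history by history, so their dose-difference maps
  are nearly free of common Monte Carlo noise. All dose-difference
  experiments in the test suite use this.

Energy bookkeeping (deposited <= entering) is checked on every run.

## Comparison tools

Percent difference maps are evaluated where the reference dose is positive;
per-ROI statistics erode masks by 0.3 mm. Misassignment fractions compare
labels by material name and tabulate confusions. Dose-error histograms use
half-open bins with a configurable zero-bin width (default 5 percentage
points, a free parameter). DVH metrics follow the "minimum dose to the
hottest x%" convention, computed as interpolated (type-7) order statistics,
so a linear dose ramp yields D95 = 0.05, D5 = 0.95, D1 = 0.99 of the
maximum exactly. `count_dose_plateaus()` counts distinct high-dose levels
(kernel-density modes above the prescription carrying >= 5% of the
considered volume) to detect the multi-level bone dose structure that
multi-bone segmentations produce.

## Problem sizes and study conditions

The native acquisition geometry (0.1034 mm voxels) is used where the
quantity demands it (the HU-anchor checks). Segmentation experiments run at
0.2 mm on 2 mm cylinder stacks - the cylinder is uniform along its axis, so
short stacks probe identical physics at a fraction of the memory. Dose
comparisons decimate the material maps to 0.4-0.6 mm and use 2e6 to 1e7
histories with correlated sampling; the rodent case uses 0.2 mm
segmentation, 0.4 mm dosing, parallel-opposed beams at 29 and 209 degrees,
a 1.4 x 1.4 cm field enclosing the target, and 2 Gy prescribed to the
tumour mask mean. The SECT instability comparison (three vs seven media) is
run on the 90 kVp scan, where the synthetic Lucite/Solid Water HU gap is
well inside two noise standard deviations - the regime in which adding
similar media destabilizes threshold segmentation.

## Known limitations

* Image model: no beam hardening, scatter or reconstruction artefacts;
  noise is Gaussian and spatially white, while real CBCT noise is textured.
  Real-data segmentation is harder than these phantoms suggest.
* Spectrum model: Kramers shape without anode self-filtration; absolute HU
  of dense media are overestimated. Use `load_spectrum()` for measured or
  externally computed spectra.
* Elemental data: parameterized, not reference tabulations; adequate for
  relative quantities, not absolute dosimetry.
* Dose engine: free-electron Compton, optional form-factor-free Rayleigh,
  kerma approximation; valid only below ~225 keV (no pair production).
* The rodent phantom is a topological stand-in; mouse-case results are
  directions and patterns, not animal-specific values.
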