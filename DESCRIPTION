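Package: kvseg
Title: Tissue Segmentation from Single- and Dual-Energy CT and its Impact
    on Kilovolt Photon Dose Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how CT-based tissue segmentation propagates into
    kilovolt photon dose calculations for pre-clinical (small-animal)
    radiotherapy. Provides a material database with radiological quantities
    (relative electron density, effective atomic number, mass attenuation and
    energy-absorption coefficients), a simple x-ray tube spectrum model,
    synthetic dual-energy CT simulation of cylindrical calibration/validation
    phantoms and a digital rodent-head phantom, single-energy (HU-density
    calibration plus thresholds) and dual-energy (Saito electron-density and
    Landry effective-atomic-number decomposition with Mahalanobis tissue
    assignment) segmentation pathways, a photon-only voxel Monte Carlo dose
    engine under the collision-kerma approximation (Woodcock tracking,
    Klein-Nishina Compton, local photoelectric absorption), and comparison
    utilities (dose-difference maps, misassignment fractions, dose-volume
    histograms with D95/D5/D1 metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
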