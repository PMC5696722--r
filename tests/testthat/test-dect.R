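test_that("the electron-density calibration is near-perfectly linear on synthetic pairs", {
  cal <- dect_cal_clean()
  expect_gte(cal$rhoe$r_squared, 0.999)
  expect_equal(cal$rhoe$b, 1.000, tolerance = 0.01)  # water: HU_L = HU_H = 0
  expect_warning(calibrate_rhoe(c(0, 10, 20, 400), c(0, 10, 20, 400),
                                c(0.9, 1, 1.05, 1.4)), "indeterminate")
})

test_that("rho_e maps recover reference electron densities on noiseless scans", {
  cal <- dect_cal_clean()
  pair <- val_pair_clean()
  rm <- rhoe_map(pair$low, pair$high, cal)
  st <- roi_statistics(rm, val_phantom(), 0.3)
  db <- load_materials()
  for (i in seq_len(nrow(st))) {
    nm <- st$material[i]
    if (nm == "Air") next
    expect_lt(abs(st$mean[i] / db[[nm]]$ref_rho_e - 1), 0.02)
  }
  # linear in the HU pair by construction
  h1 <- pair$low; h1$values <- 2 * h1$values
  h2 <- pair$high; h2$values <- 2 * h2$values
  rm2 <- rhoe_map(h1, h2, cal)
  b <- cal$rhoe$b
  expect_equal(rm2$values - b, 2 * (rm$values - b), tolerance = 1e-9)
})

test_that("the Zeff-ratio table is monotone, water-normalized and wide enough", {
  tab <- dect_cal_clean()$zeff_table
  expect_true(all(diff(tab$ratio) > 0))
  expect_equal(approx(tab$z, tab$ratio, xout = tab$z_water)$y, 1,
               tolerance = 1e-9)
  refs <- vapply(load_materials(), `[[`, numeric(1), "ref_z_eff")
  expect_true(all(refs >= min(tab$z) & refs <= max(tab$z)))
  expect_error(build_zeff_ratio_table(spec50(), spec50()), "monotone")
})

test_that("Zeff inversion closes on noiseless scans and excludes deep air", {
  cal <- dect_cal_clean()
  pair <- val_pair_clean()
  zm <- zeff_map(pair$low, pair$high, cal)
  st <- roi_statistics(zm$zeff, val_phantom(), 0.3)
  expect_lt(abs(st$mean[st$material == "Water"] / 7.477 - 1), 0.01)
  # no exclusions inside interior ROIs of a noiseless scan
  expect_equal(sum(zm$excluded & val_interior()), 0)
  # an HU pair at exactly (-1000, -1000) has no attenuation ratio
  h <- pair$low; h$values[] <- -1000
  zm2 <- zeff_map(h, h, cal)
  expect_true(all(zm2$excluded))
})

test_that("a voxel sitting exactly on a reference point gets that tissue", {
  refs <- tissue_references(scheme_preset("DECT7"))
  n <- nrow(refs)
  zv <- voxel_volume(array(refs$z_r, c(n, 1, 1)), 1, quantity = "z_eff")
  rv <- voxel_volume(array(refs$rho_r, c(n, 1, 1)), 1, quantity = "rho_e")
  rho_fit <- list(slope = 1.073, intercept = -0.04)
  mm <- assign_tissue_mahalanobis(zv, rv, refs, diag(2), rho_fit)
  expect_identical(unname(mm$palette[as.vector(mm$labels$values)]),
                   refs$material)
})

test_that("identity covariance reduces to brute-force nearest neighbour", {
  refs <- tissue_references(scheme_preset("DECT7"))
  set.seed(99)
  n <- 500
  z <- array(runif(n, 5.5, 14), c(n, 1, 1))
  r <- array(runif(n, 0.9, 1.7), c(n, 1, 1))
  zv <- voxel_volume(z, 1, quantity = "z_eff")
  rv <- voxel_volume(r, 1, quantity = "rho_e")
  rho_fit <- list(slope = 1.073, intercept = -0.04)
  mm <- assign_tissue_mahalanobis(zv, rv, refs, diag(2), rho_fit)
  # independent oracle: exhaustive Euclidean nearest neighbour
  brute <- vapply(seq_len(n), function(i) {
    d2 <- (refs$z_r - z[i])^2 + (refs$rho_r - r[i])^2
    refs$material[which.min(d2)]
  }, character(1))
  expect_identical(unname(mm$palette[as.vector(mm$labels$values)]), brute)
  # permutation invariance of the reference order
  mm2 <- assign_tissue_mahalanobis(zv, rv, refs[rev(seq_len(nrow(refs))), ],
                                   diag(2), rho_fit)
  expect_identical(mm$palette[as.vector(mm$labels$values)],
                   mm2$palette[as.vector(mm2$labels$values)])
  expect_error(assign_tissue_mahalanobis(zv, rv, refs,
                                         matrix(c(1, 1, 1, 1), 2), rho_fit),
               "singular|positive definite")
})

test_that("anisotropic noise covariance changes borderline soft-tissue labels", {
  refs <- tissue_references(c("Water", "Solid Water", "Muscle"))
  set.seed(7)
  n <- 2000
  # noisy cloud around Solid Water with Zeff noise dominating
  z <- array(7.735 + rnorm(n, 0, 0.4), c(n, 1, 1))
  r <- array(0.992 + rnorm(n, 0, 0.01), c(n, 1, 1))
  zv <- voxel_volume(z, 1, quantity = "z_eff")
  rv <- voxel_volume(r, 1, quantity = "rho_e")
  rho_fit <- list(slope = 1.073, intercept = -0.04)
  cov_aniso <- diag(c(0.4^2, 0.01^2))
  m_mah <- assign_tissue_mahalanobis(zv, rv, refs, cov_aniso, rho_fit)
  m_euc <- assign_tissue_mahalanobis(zv, rv, refs, diag(2), rho_fit)
  lab_mah <- m_mah$palette[as.vector(m_mah$labels$values)]
  lab_euc <- m_euc$palette[as.vector(m_euc$labels$values)]
  expect_gt(sum(lab_mah != lab_euc), 0)
  # the anisotropy-aware metric recovers the true medium more often
  expect_gt(mean(lab_mah == "Solid Water"), mean(lab_euc == "Solid Water"))
})

test_that("noiseless DECT7 segmentation is exact on interior scheme-media voxels", {
  mm <- segment_dect(val_pair_clean(), dect_cal_clean(), scheme_preset("DECT7"))
  ref <- reference_material_map(val_phantom())
  ph <- val_phantom()
  # inserts whose true medium is a DECT7 medium (PMMA graded as Lucite),
  # plus the Solid Water bulk
  gradeable <- erode_mask(ph$structures$bulk, 0.2, 0.4)
  for (k in c(1, 3, 4, 5, 6, 9, 10, 11, 12))
    gradeable <- gradeable |
      erode_mask(ph$structures[[paste0("insert_", k)]], 0.2, 0.4)
  mf <- misassignment_fraction(mm, ref, gradeable)
  expect_equal(mf$fraction, 0)
})
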