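test_that("cylinder phantoms have twelve ring inserts with correct materials", {
  ph <- cal_phantom()
  expect_length(grep("^insert_", names(ph$structures)), 12)
  # insert 8 of the calibration set is Water: probe its centre voxel
  ctr <- which(ph$structures$insert_8, arr.ind = TRUE)
  ctr <- round(colMeans(ctr))
  lab <- ph$labels$values[ctr[1], ctr[2], ctr[3]]
  expect_identical(ph$palette[lab], "Water")
  # area ratio of one insert to the cylinder ~ (3.5/30)^2
  frac <- sum(ph$structures$insert_1) / sum(ph$structures$body)
  expect_equal(frac, (3.5 / 30)^2, tolerance = 0.05)
  expect_error(build_cylinder_phantom("validation", spacing = 0.5),
               "too coarse")
})

test_that("synthetic HU anchors at water zero and air near -1000", {
  for (s in list(spec50(), spec90())) {
    img <- simulate_ct(val_phantom(), s, noise_sigma = 0, psf_fwhm = 0)
    st <- roi_statistics(img, val_phantom(), erosion_mm = 0.3)
    expect_lt(abs(st$mean[st$material == "Water"]), 1e-9)
    expect_lt(abs(st$mean[st$material == "Air"] - (-1000)), 2)
    expect_true(all(st$sd == 0))  # noiseless, blur-free: piecewise constant
  }
})

test_that("HU increases strictly with density at fixed composition", {
  mats <- load_materials()
  s <- spec50()
  mu_w <- effective_mu(s, water_material())
  rhos <- seq(0.2, 2, by = 0.2)
  hu <- vapply(rhos, function(r) {
    m <- material("x", r, c(H = 0.112, O = 0.888))
    1000 * (effective_mu(s, m) / mu_w - 1)
  }, numeric(1))
  expect_true(all(diff(hu) > 0))
})

test_that("dual-energy pairs are registered exactly with independent noise", {
  pair <- simulate_dect_pair(val_phantom(), spec50(), spec90(),
                             noise_sigma_low = 15, noise_sigma_high = 12,
                             seed = 4)
  expect_identical(dim(pair$low$values), dim(pair$high$values))
  expect_identical(pair$low$spacing, pair$high$spacing)
  st_l <- roi_statistics(pair$low, val_phantom(), 0.3)
  st_h <- roi_statistics(pair$high, val_phantom(), 0.3)
  # water near zero in both; high-Z media attenuate more at low energy
  expect_lt(abs(st_l$mean[st_l$material == "Water"]), 2)
  expect_lt(abs(st_h$mean[st_h$material == "Water"]), 2)
  expect_gt(st_l$mean[st_l$material == "Bone"],
            st_h$mean[st_h$material == "Bone"])
  # same seed reproduces bit-identically
  pair2 <- simulate_dect_pair(val_phantom(), spec50(), spec90(),
                              noise_sigma_low = 15, noise_sigma_high = 12,
                              seed = 4)
  expect_identical(pair$low$values, pair2$low$values)
  expect_warning(simulate_dect_pair(val_phantom(), spec50(), spec50()),
                 "degenerate")
})

test_that("injected per-material noise levels are recovered from the image", {
  sig <- phantom_noise_levels("calibration", 50)
  img <- simulate_ct(cal_phantom(), spec50(), noise_sigma = sig,
                     psf_fwhm = 0, seed = 2)
  st <- roi_statistics(img, cal_phantom(), erosion_mm = 0.3)
  for (i in seq_len(nrow(st))) {
    if (st$n_voxels[i] < 1000) next
    expect_lt(abs(st$sd[i] / sig[[st$material[i]]] - 1), 0.10)
  }
})

test_that("the rodent head phantom has the six ICRU tissues and a straddling tumour", {
  ph <- fx("rodent", build_rodent_head_phantom(spacing = 0.25))
  used <- sort(unique(ph$palette[as.vector(unique(ph$labels$values))]))
  expect_setequal(used, c("Air", "ICRU Adipose", "Brain", "Spongiosa",
                          "Cranium", "Cortical Bone"))
  st <- ph$structures
  # the cord canal lies within the region enclosed by the vertebra
  spong <- ph$labels$values == which(ph$palette == "Spongiosa")
  expect_true(any(st$spinal_cord))
  expect_true(sum(st$tumour & st$brain) > 0)
  expect_true(sum(st$tumour & st$spinal_cord) > 0)
  # the cord canal is enclosed by the spongiosa vertebra: on each axial
  # slice the cord's in-plane extent lies strictly inside the vertebra's
  k_mid <- round(dim(st$spinal_cord)[3] / 2)
  cord_sl <- which(st$spinal_cord[, , k_mid], arr.ind = TRUE)
  sp_sl <- which(spong[, , k_mid], arr.ind = TRUE)
  expect_true(min(sp_sl[, 1]) < min(cord_sl[, 1]) &&
              max(sp_sl[, 1]) > max(cord_sl[, 1]) &&
              min(sp_sl[, 2]) < min(cord_sl[, 2]) &&
              max(sp_sl[, 2]) > max(cord_sl[, 2]))
})

test_that("volumes round-trip through NIfTI", {
  v <- voxel_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), spacing = c(0.2, 0.2, 0.3),
                    quantity = "HU")
  tf <- tempfile(fileext = ".nii.gz")
  write_volume(v, tf)
  v2 <- read_volume(tf, quantity = "HU")
  expect_equal(v2$values, v$values, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
})
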