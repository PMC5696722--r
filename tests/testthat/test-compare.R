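make_dose <- function(values, spacing = 1) {
  voxel_volume(values, spacing, quantity = "dose")
}

test_that("dose-difference maps are percentages against the reference", {
  ref <- make_dose(array(2, c(4, 4, 4)))
  expect_true(all(dose_difference_map(ref, ref)$values == 0))
  tst <- make_dose(array(2.4, c(4, 4, 4)))
  expect_true(all(abs(dose_difference_map(tst, ref)$values - 20) < 1e-12))
  ref0 <- ref; ref0$values[1, , ] <- 0  # unscored air
  dd <- dose_difference_map(tst, ref0)
  expect_true(all(is.na(dd$values[1, , ])))
  expect_error(dose_difference_map(tst, make_dose(array(1, c(3, 3, 3)))),
               "mismatch")
})

test_that("ROI statistics of difference maps honour erosion and masks", {
  dd <- make_dose(array(10, c(10, 10, 10)))
  dd$quantity <- "other"
  masks <- list(a = array(TRUE, c(10, 10, 10)))
  st <- roi_dose_stats(dd, masks, erosion_mm = 0)
  expect_equal(st$mean, 10)
  expect_equal(st$sd, 0)
  st2 <- roi_dose_stats(dd, masks, erosion_mm = 2)
  expect_lt(st2$n_voxels, st$n_voxels)
  expect_equal(st2$mean, 10)
  nav <- dd; nav$values[] <- NA_real_
  expect_error(roi_dose_stats(nav, masks, 0), "no evaluable")
})

test_that("misassignment fractions count differing labels by name", {
  lab <- array(1L, c(4, 4, 2)); lab[3:4, , ] <- 2L
  rho <- array(1, c(4, 4, 2))
  a <- material_map(lab, c("Water", "Bone"), rho, spacing = 1)
  expect_equal(misassignment_fraction(a, a)$fraction, 0)
  flip <- array(3L - lab, dim = dim(lab))
  b <- material_map(flip, c("Water", "Bone"), rho, spacing = 1)
  expect_equal(misassignment_fraction(b, a)$fraction, 1)
  # checkerboard half-swap
  chk <- lab
  sel <- (slice.index(lab, 1) + slice.index(lab, 2)) %% 2 == 0
  chk[sel] <- 3L - chk[sel]
  cmap <- material_map(chk, c("Water", "Bone"), rho, spacing = 1)
  expect_equal(misassignment_fraction(cmap, a)$fraction, 0.5)
  # palettes in different order still compare by material name
  lab_swapped <- array(3L - lab, dim = dim(lab))
  b2 <- material_map(lab_swapped, c("Bone", "Water"), rho, spacing = 1)
  expect_equal(misassignment_fraction(b2, a)$fraction, 0)
})

test_that("dose-error histograms use half-open bins and report the zero bin", {
  z <- make_dose(array(0, c(5, 5, 5))); z$quantity <- "other"
  region <- array(TRUE, c(5, 5, 5))
  h <- dose_error_histogram(list(m = z), region)
  expect_equal(unname(h$zero_bin_fraction["m"]), 1)
  two <- z; two$values[1:50] <- 20
  h2 <- dose_error_histogram(list(m = two), region, breaks = seq(-2.5, 32.5, 5))
  expect_equal(sum(h2$counts > 0), 2)
  expect_equal(h2$counts[h2$breaks[-length(h2$breaks)] == 17.5], 50)
  # half-open convention: a value exactly on an edge belongs to the upper bin
  edge <- z; edge$values[] <- 2.5
  h3 <- dose_error_histogram(list(m = edge), region,
                             breaks = c(-2.5, 2.5, 7.5))
  expect_equal(unname(h3$counts[1, ]), c(0, 125))
})

test_that("DVH metrics are interpolated order statistics", {
  u <- make_dose(array(2, c(6, 6, 6)))
  mask <- array(TRUE, c(6, 6, 6))
  dv <- compute_dvh(u, mask)
  expect_equal(unname(dv$metrics), rep(2, 5))
  # linear ramp over equal-volume voxels: closed-form order statistics
  ramp <- make_dose(array(seq(0, 1, length.out = 101), c(101, 1, 1)))
  dvr <- compute_dvh(ramp, array(TRUE, c(101, 1, 1)))
  expect_equal(unname(dvr$metrics["D95"]), 0.05)
  expect_equal(unname(dvr$metrics["D5"]), 0.95)
  expect_equal(unname(dvr$metrics["D1"]), 0.99)
  one <- make_dose(array(3, c(1, 1, 1)))
  dv1 <- compute_dvh(one, array(TRUE, c(1, 1, 1)))
  expect_equal(unname(dv1$metrics), rep(3, 5))
  expect_error(compute_dvh(one, array(FALSE, c(1, 1, 1))), "empty")
})

test_that("DVH curves are monotone with ordered metrics", {
  set.seed(31)
  for (i in 1:5) {
    d <- make_dose(array(rgamma(4^3, shape = 2, scale = i), c(4, 4, 4)))
    dv <- compute_dvh(d, array(TRUE, c(4, 4, 4)))
    expect_true(all(diff(dv$cumulative_volume_fraction) <= 0))
    expect_equal(dv$cumulative_volume_fraction[1], 1)
    m <- dv$metrics
    expect_lte(m[["D95"]], m[["D5"]])
    expect_lte(m[["D5"]], m[["D1"]])
    expect_lte(m[["D1"]], m[["max"]])
    expect_lte(m[["D95"]], m[["mean"]])
    expect_lte(m[["mean"]], m[["D1"]])
  }
})

test_that("plateau counting separates well-split dose levels", {
  set.seed(5)
  lv <- c(rnorm(400, 3, 0.1), rnorm(300, 5, 0.12), rnorm(200, 7, 0.15))
  d <- make_dose(array(c(lv, rep(0.5, 100)), c(10, 10, 10)))
  mask <- array(TRUE, c(10, 10, 10))
  expect_equal(count_dose_plateaus(d, mask, above = 2), 3)
  single <- make_dose(array(rnorm(1000, 4, 0.2), c(10, 10, 10)))
  expect_equal(count_dose_plateaus(single, mask, above = 2), 1)
})
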