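test_that("crescent background averages the image over the crescent tube", {
  # constant field: the mean is the constant whatever the crescent shape
  v <- pet_volume(array(1.3, c(48, 48, 24)), test_spacing)
  bg <- build_crescent_background(v, "right")
  expect_equal(bg$suv_mean, 1.3)
  bg2 <- build_crescent_background(v, "left", slice_index = 10,
                                   params = list(inner_radius_mm = 15,
                                                 outer_radius_mm = 30,
                                                 span_deg = 90,
                                                 n_slices_extruded = 2L))
  expect_equal(bg2$suv_mean, 1.3)
  expect_equal(bg2$n_slices_extruded, 2L)
  # extrusion: 5 slices of identical footprint
  per_slice <- apply(bg2$mask$data, 3, sum)
  expect_equal(sum(per_slice > 0), 5)
  expect_equal(length(unique(per_slice[per_slice > 0])), 1L)
})

test_that("crescent mean matches a brute-force mean over mask voxels", {
  spec <- small_spec(psf_fwhm_mm = 2, noise_sd_suv = 0.05, seed = 21)
  ph <- make_static_phantom(spec)
  bg <- build_crescent_background(ph$volume, "right")
  acc <- 0; n <- 0
  d <- dim(ph$volume$data)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (bg$mask$data[i, j, k]) { acc <- acc + ph$volume$data[i, j, k]; n <- n + 1 }
  expect_equal(bg$suv_mean, acc / n)
  expect_lt(abs(bg$suv_mean - 1.0), 3 * spec$noise_sd_suv)
  # the crescent sits entirely in the contralateral (left) hemisphere
  idx <- which(bg$mask$data, arr.ind = TRUE)
  x_mm <- (idx[, 1] - 0.5) * ph$volume$spacing_mm[1]
  expect_true(all(x_mm < d[1] * ph$volume$spacing_mm[1] / 2))
})

test_that("a crescent reaching the lesion hemisphere is rejected", {
  v <- pet_volume(array(1, c(48, 48, 24)), test_spacing)
  expect_error(build_crescent_background(v, "right",
                                         params = list(span_deg = 270)),
               "midline")
  expect_error(build_crescent_background(v, "right", slice_index = 99),
               "outside the grid")
})

test_that("thresholding keeps exactly the sphere voxels at or above 1.6 x background", {
  spec <- small_spec(lesion_tbr = 2.0)
  ph <- make_static_phantom(spec)
  bg <- build_crescent_background(ph$volume, "right")
  d <- threshold_gtv0(ph$volume, spec$lesion_center_mm, 18, bg)
  expect_equal(d$threshold_suv, 1.6 * bg$suv_mean)
  expect_identical(d$gtv0$data, ph$truth$lesion_mask$data)
  expect_true(all(d$gtv0$data[d$gtv0$data] ))
  expect_true(all(d$gtv0$data == (d$gtv0$data & d$static_sphere$data)))
  expect_false(d$empty_gtv0)
})

test_that("sub-threshold spheres are flagged, not errors", {
  v <- pet_volume(array(1.59, c(32, 32, 16)), c(2, 2, 2))
  bg <- structure(list(suv_mean = 1.0), class = "fet_background")
  d <- threshold_gtv0(v, c(32, 32, 16), 10, bg)
  expect_true(d$empty_gtv0)
  expect_equal(sum(d$gtv0$data), 0)
})

test_that("noisy-phantom GTV0 equals a brute-force voxel scan", {
  spec <- small_spec(psf_fwhm_mm = 2, noise_sd_suv = 0.1, seed = 31)
  ph <- make_static_phantom(spec)
  bg <- build_crescent_background(ph$volume, "right")
  ctr <- spec$lesion_center_mm; rad <- 20
  d <- threshold_gtv0(ph$volume, ctr, rad, bg)
  dm <- dim(ph$volume$data)
  ref <- array(FALSE, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    ctr_vox <- (c(i, j, k) - 0.5) * test_spacing
    inside <- sum((ctr_vox - ctr)^2) <= rad^2
    if (inside && ph$volume$data[i, j, k] >= 1.6 * bg$suv_mean)
      ref[i, j, k] <- TRUE
  }
  expect_identical(d$gtv0$data, ref)
})

test_that("edits are applied in order and fully audited", {
  base <- small_spec(lesion_volume_cm3 = 8)
  spec <- small_spec(lesion_volume_cm3 = 8, confounder_volume_cm3 = 0.5,
                     confounder_center_mm = base$lesion_center_mm +
                       c(-22, 0, 0))
  ph <- make_static_phantom(spec)
  bg <- build_crescent_background(ph$volume, "right")
  d <- threshold_gtv0(ph$volume, spec$lesion_center_mm, 30, bg)
  # threshold picked up lesion + confounder as separate components
  expect_identical(d$gtv0$data,
                   ph$truth$lesion_mask$data | ph$truth$confounder_mask$data)
  # no edits: BTV is GTV0
  d0 <- edit_btv(d, list())
  expect_identical(d0$btv$data, d0$gtv0$data)
  expect_equal(nrow(d0$edit_log), 0)
  # removing the confounder component recovers the true lesion
  seedvox <- which(ph$truth$confounder_mask$data, arr.ind = TRUE)[1, ]
  d1 <- edit_btv(d, list(list(op = "remove_component",
                              seed_voxel = seedvox)), image = ph$volume)
  expect_identical(d1$btv$data, ph$truth$lesion_mask$data)
  expect_equal(d1$edit_log$op, "remove_component")
  expect_true(d1$edit_log$voxels_changed > 0)
  # adding a sub-threshold region lowers TBR_mean and logs a warning
  add <- array(FALSE, dim(ph$volume$data))
  lowvox <- which(ph$truth$brain_mask$data & !d$gtv0$data)[1:500]
  add[lowvox] <- TRUE
  d2 <- edit_btv(d1, list(list(op = "add_region", mask = add)),
                 image = ph$volume)
  expect_match(d2$edit_log$warning[1], "below the SUV threshold")
  tb1 <- compute_tbr(ph$volume, d1$btv, bg)
  tb2 <- compute_tbr(ph$volume, d2$btv, bg)
  expect_lt(tb2$tbr_mean, tb1$tbr_mean)
  expect_lt(tb2$tbr_mean, 1.6)   # necrosis-like inclusion drags it down
  expect_gte(tb1$tbr_mean, 1.6)  # all-threshold-passing mask stays >= 1.6
})

test_that("TBR statistics follow their definitions with deterministic ties", {
  v <- pet_volume(array(c(2, 3, 1, 1), c(2, 2, 1)), c(2, 2, 3))
  bg <- structure(list(suv_mean = 1.25), class = "fet_background")
  m <- voi_mask(array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1)), c(2, 2, 3))
  tb <- compute_tbr(v, m, bg)
  expect_equal(tb$tbr_max, 2.4)
  expect_equal(tb$tbr_mean, 2.0)
  expect_equal(tb$suv_max, 3)
  expect_equal(tb$suv_max_location, c(2L, 1L, 1L))
  # tie in SUV_max: the lowest linear index wins
  vt <- pet_volume(array(c(3, 3, 1, 1), c(2, 2, 1)), c(2, 2, 3))
  mt <- voi_mask(array(TRUE, c(2, 2, 1)), c(2, 2, 3))
  expect_equal(compute_tbr(vt, mt, bg)$suv_max_location, c(1L, 1L, 1L))
  expect_error(compute_tbr(v, voi_mask(array(FALSE, c(2, 2, 1)),
                                       c(2, 2, 3), allow_empty = TRUE), bg),
               "empty")
})

test_that("TBRs are invariant under global image rescaling", {
  spec <- small_spec(psf_fwhm_mm = 2, noise_sd_suv = 0.03, seed = 17)
  ph <- make_static_phantom(spec)
  run <- function(img) {
    d <- delineate(img, spec$lesion_center_mm, 20)
    c(d$tbr_max, d$tbr_mean)
  }
  a <- run(ph$volume)
  scaled <- pet_volume(ph$volume$data * 3.7, ph$volume$spacing_mm)
  b <- run(scaled)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("noiseless recovery: TBR parameters are recovered exactly", {
  spec <- small_spec(lesion_tbr = 2.0)
  ph <- make_static_phantom(spec)
  d <- delineate(ph$volume, spec$lesion_center_mm, 18)
  expect_identical(d$btv$data, ph$truth$lesion_mask$data)
  expect_equal(d$tbr_mean, 2.0, tolerance = 1e-12)
  expect_equal(d$tbr_max, 2.0, tolerance = 1e-12)
})
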