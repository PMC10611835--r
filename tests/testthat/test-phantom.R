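test_that("noiseless blur-free phantom is piecewise constant at the specified SUVs", {
  spec <- small_spec(lesion_tbr = 2.0)
  ph <- make_static_phantom(spec)
  brain <- ph$truth$brain_mask$data
  lesion <- ph$truth$lesion_mask$data
  conf <- ph$truth$confounder_mask$data
  expect_true(all(ph$volume$data[lesion] == 2.0))
  expect_true(all(ph$volume$data[brain & !lesion & !conf] == 1.0))
  expect_true(all(ph$volume$data[conf] == 2.0))
  expect_true(all(ph$volume$data[!brain & !conf & !lesion] == 0))
})

test_that("lesion voxelisation hits the requested volume within one voxel", {
  # a large-lesion benchmark volume on the default clinical grid
  spec <- phantom_spec(lesion_volume_cm3 = 64.69, psf_fwhm_mm = 0,
                       noise_sd_suv = 0, seed = 2)
  ph <- make_static_phantom(spec)
  vox <- prod(spec$spacing_mm) / 1000
  expect_lt(abs(ph$truth$true_volume_cm3 - 64.69), vox)
  expect_equal(ph$truth$true_volume_cm3,
               mask_volume_cm3(ph$truth$lesion_mask))
  # lesion and confounder are disjoint
  expect_false(any(ph$truth$lesion_mask$data &
                     ph$truth$confounder_mask$data))
})

test_that("identical seeds give bit-identical phantoms", {
  spec <- small_spec(psf_fwhm_mm = 3, noise_sd_suv = 0.05, seed = 9)
  a <- make_static_phantom(spec)
  b <- make_static_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  spec2 <- small_spec(psf_fwhm_mm = 3, noise_sd_suv = 0.05, seed = 10)
  expect_false(identical(make_static_phantom(spec2)$volume$data,
                         a$volume$data))
})

test_that("spec invariants are enforced", {
  expect_error(small_spec(lesion_tbr = 1.5), "1.6")
  expect_error(small_spec(background_mean_suv = 0), "positive")
  expect_error(small_spec(noise_sd_suv = -1), "non-negative")
  expect_error(
    phantom_spec(grid_shape = c(32, 32, 16),
                 lesion_center_mm = c(2, 2, 2), lesion_volume_cm3 = 30,
                 psf_fwhm_mm = 0, noise_sd_suv = 0),
    "outside the grid")
})

test_that("dynamic phantom realises the three canonical TAC shapes", {
  spec <- small_spec(lesion_volume_cm3 = 8, lesion_tbr = 2.3,
                     noise_sd_suv = 0.01, seed = 4)
  times <- seq(2.5, 37.5, by = 5)
  lesion_mean <- function(dyn)
    vapply(dyn$frames, function(f) mean(f$data[dyn$truth$lesion_mask$data]),
           numeric(1))
  d1 <- make_dynamic_phantom(spec, "I", times)
  expect_true(all(diff(lesion_mean(d1)) > 0))
  d3 <- make_dynamic_phantom(spec, "III", times)
  m3 <- lesion_mean(d3)
  peak <- which.max(m3)
  expect_lte(times[peak], 20)
  expect_true(all(diff(m3[peak:length(m3)]) < 0))
  # background time course constant to within the noise scale
  bg_vox <- d3$truth$brain_mask$data & !d3$truth$lesion_mask$data
  bg_mean <- vapply(d3$frames, function(f) mean(f$data[bg_vox]), numeric(1))
  expect_lt(max(abs(bg_mean - mean(bg_mean))), spec$noise_sd_suv)
  expect_error(make_dynamic_phantom(spec, "IV", times), "arg")
  expect_error(make_dynamic_phantom(spec, "I", c(5, 3, 10)),
               "strictly increasing")
})

test_that("zero-variance rater model yields identical contours", {
  spec <- small_spec(seed = 6)
  ph <- make_static_phantom(spec)
  mdl <- rater_model(n_raters = 3, boundary_jitter_mm = 0,
                     sphere_offset_mm = 0, p_include_confounder = 0,
                     seed = 11)
  masks <- make_rater_cohort(ph$truth, ph$volume, mdl)
  expect_length(masks, 3)
  expect_identical(masks[[1]]$data, masks[[2]]$data)
  expect_identical(masks[[1]]$data, masks[[3]]$data)
  expect_equal(dsc(masks[[1]], masks[[2]]), 1)
  # and the zero-variance contour is the true lesion (noiseless phantom)
  expect_identical(masks[[1]]$data, ph$truth$lesion_mask$data)
})

test_that("forced confounder inclusion puts the confounder in every mask", {
  # place the confounder a fixed offset from the lesion so that it falls
  # inside the search sphere used below
  base <- small_spec(lesion_volume_cm3 = 8)
  spec <- small_spec(
    lesion_volume_cm3 = 8, confounder_volume_cm3 = 0.5,
    confounder_center_mm = base$lesion_center_mm + c(-22, 0, 0),
    seed = 8)
  ph <- make_static_phantom(spec)
  mdl <- rater_model(n_raters = 3, boundary_jitter_mm = 0,
                     sphere_offset_mm = 0, p_include_confounder = 1,
                     seed = 2)
  masks <- make_rater_cohort(ph$truth, ph$volume, mdl,
                             sphere_radius_mm = 30)
  for (m in masks)
    expect_true(all(m$data[ph$truth$confounder_mask$data]))
  # with removal enabled the same cohort recovers the lesion alone
  mdl0 <- rater_model(n_raters = 3, boundary_jitter_mm = 0,
                      sphere_offset_mm = 0, p_include_confounder = 0,
                      seed = 2)
  masks0 <- make_rater_cohort(ph$truth, ph$volume, mdl0,
                              sphere_radius_mm = 30)
  expect_identical(masks0[[1]]$data, ph$truth$lesion_mask$data)
})

test_that("mean pairwise DSC does not increase with sphere placement error", {
  offsets <- c(0, 2.5, 5)
  mean_dsc <- numeric(length(offsets))
  for (oi in seq_along(offsets)) {
    vals <- numeric(0)
    for (s in 1:20) {
      spec <- small_spec(lesion_volume_cm3 = 8, psf_fwhm_mm = 2,
                         noise_sd_suv = 0.02, lesion_tbr = 2.2,
                         seed = 100 + s)
      ph <- make_static_phantom(spec)
      mdl <- rater_model(n_raters = 2, boundary_jitter_mm = 0,
                         sphere_offset_mm = offsets[oi],
                         p_include_confounder = 0, seed = 1000 + s)
      masks <- make_rater_cohort(ph$truth, ph$volume, mdl,
                                 sphere_radius_mm = 14)
      vals <- c(vals, dsc(masks[[1]], masks[[2]]))
    }
    mean_dsc[oi] <- mean(vals)
  }
  expect_true(all(diff(mean_dsc) <= 0))
})
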