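test_that("straight tube width is recovered within one pixel pitch", {
  v <- array(0, c(80, 40, 5))
  v[10:70, 18:23, 3] <- 100            # 6 px wide at 0.05 um = 0.30 um
  st <- image_stack(v, 0.05, 0.13)
  tm <- measure_threads(st, 50)
  expect_equal(tm$width_mean_um, 0.30, tolerance = 0.05 / 0.30)
  expect_error(measure_threads(st, 200), "no thread signal")
})

test_that("two tubes of different width are ordered correctly", {
  z1 <- render_zerfall_scene(0.25, 30e9, 0, globular_fraction = 0,
                             n_threads = 2, rng_seed = 5)
  z2 <- render_zerfall_scene(0.35, 30e9, 0, globular_fraction = 0,
                             n_threads = 2, rng_seed = 5)
  w1 <- measure_threads(z1$stack, compute_threshold(z1$stack, "otsu"),
                        psf_sigma_xy_um = 0.1)$width_mean_um
  w2 <- measure_threads(z2$stack, compute_threshold(z2$stack, "otsu"),
                        psf_sigma_xy_um = 0.1)$width_mean_um
  expect_lt(w1, w2)
})

test_that("random-path threads rendered at 0.30 um measure inside the 0.25-0.35 um band", {
  ws <- vapply(1:5, function(s) {
    z <- render_zerfall_scene(0.30, 30e9, 0, globular_fraction = 0,
                              n_threads = 3, rng_seed = s)
    measure_threads(z$stack, compute_threshold(z$stack, "otsu"),
                    psf_sigma_xy_um = 0.1)$width_mean_um
  }, numeric(1))
  expect_gte(mean(ws), 0.25)
  expect_lte(mean(ws), 0.35)
})

test_that("well-separated puncta are counted exactly and carry 1C-equivalent fluorescence", {
  z <- render_zerfall_scene(0.30, 50 * 34e6, n_puncta = 50,
                            globular_fraction = 0, n_threads = 0,
                            shape = c(300, 300, 14), rng_seed = 11)
  p <- detect_puncta(z$stack)
  expect_equal(nrow(p), 50)
  one_c <- 34e6 * (110000 / 34e6)
  expect_equal(median(p$total_fluor), one_c, tolerance = 0.15)
  expect_lte(sum(p$total_fluor), sum(z$stack$voxels) + 1e-9)
  # fluorescence-sorted output
  expect_true(all(diff(p$total_fluor) <= 1e-9))
  # empty input and bad ranges
  expect_equal(nrow(detect_puncta(image_stack(array(0, c(20, 20, 4)),
                                              0.05, 0.13))), 0)
  expect_error(detect_puncta(z$stack, diameter_range_um = c(1, 0.4)),
               "increasing")
})

test_that("puncta-to-gamete ratios reproduce the tabulated comparison", {
  pars <- stage_params()
  g <- pars[pars$stage == "gamete", ]
  s <- pars[pars$stage == "haploid_complement", ]
  r <- puncta_vs_gametes(
    data.frame(total_fluor = s$fluor_med_mf * 1e6, volume_um3 = s$vol_med),
    data.frame(total_fluor = g$fluor_med_mf * 1e6, volume_um3 = g$vol_med))
  expect_equal(r$volume_ratio, 21)
  expect_equal(r$fluor_ratio, 0.15 / 0.11, tolerance = 1e-9)
  same <- data.frame(total_fluor = c(1, 2), volume_um3 = c(3, 4))
  both <- puncta_vs_gametes(same, same)
  expect_equal(both$fluor_ratio, 1)
  expect_equal(both$volume_ratio, 1)
  expect_error(puncta_vs_gametes(same[0, ], same), "non-empty")
})

test_that("whole-cell fluorescence is conserved through fragmentation", {
  z <- render_zerfall_scene(0.30, 300e9, n_puncta = 15, rng_seed = 3)
  whole <- measure_whole_cell(z$stack, array(TRUE, dim(z$stack$voxels)))
  expect_equal(whole, sum(z$ground_truth$total_fluor), tolerance = 0.10)
  # with shot noise and background the identity still holds within 10%
  zn <- render_zerfall_scene(0.30, 300e9, n_puncta = 15,
                             photon_scale = 1, background = 0.5,
                             rng_seed = 3)
  d <- dim(zn$stack$voxels)
  inner <- array(FALSE, d)
  inner[2:(d[1] - 1), 2:(d[2] - 1), ] <- TRUE
  whole_n <- measure_whole_cell(zn$stack, inner)
  expect_equal(whole_n, sum(zn$ground_truth$total_fluor),
               tolerance = 0.10)
})

test_that("structure classes are assigned by shape", {
  z <- render_zerfall_scene(0.30, 60e9, n_puncta = 4,
                            globular_fraction = 0.4, n_globular = 2,
                            n_threads = 1, min_separation_um = 2,
                            rng_seed = 12)
  cls <- classify_structures(z$stack,
                             compute_threshold(z$stack, "otsu_log"))
  expect_true(any(cls$structure_class == "thread"))
  expect_true(any(cls$structure_class == "punctum"))
  expect_true(any(cls$structure_class == "globular"))
})
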