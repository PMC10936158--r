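test_that("rendered intensity equals dna_bp * fluor_per_bp and blur conserves it", {
  sc <- sharp_sphere_scene()
  r <- render_stack(sc)
  expected <- 34e6 * sc$nuclei[[1]]$fluor_per_bp
  expect_equal(sum(r$stack$voxels), expected, tolerance = 0.01)
  expect_equal(r$ground_truth$total_fluor, expected)

  blurred <- scene_spec(c(60, 60, 30), sc$nuclei, rng_seed = 1)
  rb <- render_stack(blurred)
  expect_equal(sum(rb$stack$voxels), expected, tolerance = 0.005)
})

test_that("per-nucleus integrated intensity is conserved across architectures", {
  for (arch in c("H", "HDP", "V")) {
    sp <- nucleus_spec(c(4, 4, 3), 2, arch, dna_bp = 5e8)
    sc <- scene_spec(c(40, 40, 24), list(sp), voxel_size_xy = 0.2,
                     voxel_size_z = 0.26, psf_sigma_xy = 0,
                     psf_sigma_z = 0, rng_seed = 2)
    r <- render_stack(sc)
    expect_equal(sum(r$stack$voxels), 5e8 * sp$fluor_per_bp,
                 tolerance = 0.01, label = paste("architecture", arch))
  }
})

test_that("rendering is bit-reproducible under a fixed seed", {
  sc <- scene_spec(c(40, 40, 20),
                   list(nucleus_spec(c(2, 2, 1.3), 1, "V", dna_bp = 1e8)),
                   photon_scale = 1, read_noise_sd = 0.5, rng_seed = 99)
  r1 <- render_stack(sc)
  r2 <- render_stack(sc)
  expect_identical(r1$stack$voxels, r2$stack$voxels)
})

test_that("a nucleus outside the stack and bad scene parameters are rejected", {
  sp_out <- nucleus_spec(c(50, 50, 50), 1, "H", dna_bp = 1e6)
  sc <- scene_spec(c(30, 30, 10), list(sp_out))
  expect_error(render_stack(sc), "outside stack bounds")
  expect_error(scene_spec(c(30, 30, 10), psf_sigma_xy = -1), "sigma")
  expect_error(nucleus_spec(c(1, 1, 1), -2, "H", dna_bp = 1e6),
               "semi_axes")
  expect_error(nucleus_spec(c(1, 1, 1), 1, "H", dna_bp = 0), "dna_bp")
})

test_that("V-architecture ring-to-core contrast survives the PSF", {
  sp <- nucleus_spec(rep(6, 3), 4.5, "V", dna_bp = 1000 * 34e6,
                     n_chromosomes = 0)
  sc <- scene_spec(c(22, 22, 14), list(sp), voxel_size_xy = 0.55,
                   voxel_size_z = 0.72, rng_seed = 9)
  rr <- render_stack(sc)
  thr <- compute_threshold(rr$stack, "otsu")
  objs <- segment_nuclei(rr$stack, thr)
  mask <- object_mask(rr$stack, thr, objs[which.max(objs$voxel_count), ])
  pr <- radial_profile(rr$stack, mask, 10)
  iv <- pr$intensity[, 1]
  shell <- mean(iv[pr$bin_centers >= 0.7 & pr$bin_centers <= 0.9],
                na.rm = TRUE)
  core <- mean(iv[pr$bin_centers <= 0.5], na.rm = TRUE)
  expect_gte(shell / core, 0.8 / sp$core_dim_factor)
})

test_that("stage populations reproduce the packaged medians and quartiles", {
  pars <- stage_params()
  for (stage in c("gamete", "zygote", "multinuc_adult_V1")) {
    specs <- sample_stage_population(stage, 4000, rng_seed = 11)
    truth <- attr(specs, "truth")
    row <- pars[pars$stage == stage, ]
    expect_equal(median(truth$c_value), row$c_med, tolerance = 0.10)
    expect_equal(median(truth$volume_um3), row$vol_med, tolerance = 0.10)
    expect_equal(unname(quantile(truth$c_value, 0.25)), row$c_q25,
                 tolerance = 0.15)
    expect_equal(unname(quantile(truth$c_value, 0.75)), row$c_q75,
                 tolerance = 0.15)
    expect_equal(unname(quantile(truth$volume_um3, 0.25)), row$vol_q25,
                 tolerance = 0.15)
    expect_equal(unname(quantile(truth$volume_um3, 0.75)), row$vol_q75,
                 tolerance = 0.15)
  }
})

test_that("population sampling handles edge cases", {
  expect_error(sample_stage_population("not_a_stage", 5),
               "valid stages")
  empty <- sample_stage_population("gamete", 0)
  expect_length(empty, 0)
  expect_equal(nrow(attr(empty, "truth")), 0)
  # dna_bp ties C to the configured haploid genome size
  specs <- sample_stage_population("gamete", 10, rng_seed = 3,
                                   genome_size_bp_1c = 10e6)
  truth <- attr(specs, "truth")
  expect_equal(truth$dna_bp, truth$c_value * 10e6)
})

test_that("zerfall scenes echo thread width, honour n_puncta = 0 and warn when under-resolved", {
  z <- render_zerfall_scene(0.30, 10e9, n_puncta = 0,
                            globular_fraction = 0, n_threads = 1,
                            rng_seed = 4)
  gt <- z$ground_truth
  expect_true(all(gt$type == "thread"))
  expect_equal(unique(gt$width_um), 0.30)
  expect_warning(
    render_zerfall_scene(0.08, 1e9, 0, globular_fraction = 0,
                         n_threads = 1, shape = c(80, 80, 8),
                         rng_seed = 1),
    "under-resolved")
  expect_error(render_zerfall_scene(0.3, 1e9, n_puncta = -1), "n_puncta")
})
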