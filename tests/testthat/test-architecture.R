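# One mid-sized nucleus per architecture, reused across tests.
fix_H <- render_one_nucleus("H", 150, 21)
fix_HDP <- render_one_nucleus("HDP", 51, 22)
fix_V <- render_one_nucleus("V", 710, 23)

test_that("radial profiles are flat for uniform spheres and ring-shaped for V nuclei", {
  pr <- radial_profile(fix_H$stack, fix_H$mask, 10)
  iv <- pr$intensity[, 1]
  inner <- iv[pr$bin_centers <= 0.7]
  expect_lt(diff(range(inner)) / mean(inner), 0.10)
  expect_equal(sum(pr$counts), sum(fix_H$mask))

  prv <- radial_profile(fix_V$stack, fix_V$mask, 10)
  ivv <- prv$intensity[, 1]
  outer_mean <- mean(ivv[prv$bin_centers >= 0.7 & prv$bin_centers <= 0.9],
                     na.rm = TRUE)
  inner_mean <- mean(ivv[prv$bin_centers <= 0.4], na.rm = TRUE)
  expect_gt(outer_mean, 2 * inner_mean)

  expect_error(radial_profile(fix_H$stack, fix_H$mask, 1), "n_bins")
  tiny <- array(FALSE, dim(fix_H$mask)); tiny[5, 5, 5] <- TRUE
  expect_warning(radial_profile(fix_H$stack, tiny, 4), "unstable")
})

test_that("peripherality separates the three architectures and ignores gain", {
  P_H <- peripherality_index(radial_profile(fix_H$stack, fix_H$mask, 10))
  P_HDP <- peripherality_index(radial_profile(fix_HDP$stack,
                                              fix_HDP$mask, 10))
  P_V <- peripherality_index(radial_profile(fix_V$stack, fix_V$mask, 10))
  expect_lt(P_H, P_HDP)
  expect_lt(P_HDP, P_V)
  expect_equal(classify_architecture(c(P_H, P_HDP, P_V)),
               c("H", "HDP", "V"))
  # multiplying intensities by a constant leaves P unchanged
  scaled <- image_stack(fix_V$stack$voxels * 13, fix_V$stack$voxel_size_xy,
                        fix_V$stack$voxel_size_z)
  expect_equal(peripherality_index(radial_profile(scaled, fix_V$mask, 10)),
               P_V)
  expect_error(peripherality_index(radial_profile(fix_H$stack, fix_H$mask,
                                                  10),
                                   core_cut = 0.9, shell_cut = 0.8),
               "core_cut")
  expect_error(classify_architecture(-1), "positive")
})

test_that("classifier reaches 95% on noiseless renders and 85% with shot noise", {
  run_batch <- function(noisy) {
    set.seed(31)
    vols <- list(H = runif(20, 80, 300), HDP = runif(20, 25, 100),
                 V = runif(20, 400, 3000))
    correct <- 0L
    for (arch in names(vols)) {
      for (k in seq_len(20)) {
        fx <- render_one_nucleus(arch, vols[[arch]][k],
                                 seed = 1000 * match(arch, names(vols)) + k,
                                 noisy = noisy)
        pr <- suppressWarnings(radial_profile(fx$stack, fx$mask, 10))
        call <- classify_architecture(peripherality_index(pr))
        if (call == arch) correct <- correct + 1L
      }
    }
    correct / 60
  }
  expect_gte(run_batch(FALSE), 0.95)
  expect_gte(run_batch(TRUE), 0.85)
})

test_that("DNA and RNA channels anticorrelate in vegetative nuclei", {
  # DNA: bright ring; RNA: signal concentrated in the DNA-poor core
  geom <- list(shape = c(22, 22, 14), vx = 0.55, vz = 0.72)
  dna <- render_stack(scene_spec(geom$shape,
    list(nucleus_spec(rep(6, 3), 4.5, "V", dna_bp = 1000 * 34e6)),
    voxel_size_xy = geom$vx, voxel_size_z = geom$vz, rng_seed = 2))
  rna <- render_stack(scene_spec(geom$shape,
    list(nucleus_spec(rep(6, 3), 4.5 * 0.6, "H", dna_bp = 100 * 34e6)),
    voxel_size_xy = geom$vx, voxel_size_z = geom$vz, rng_seed = 2))
  arr <- array(c(dna$stack$voxels, rna$stack$voxels),
               c(dim(dna$stack$voxels), 2))
  two <- image_stack(arr, geom$vx, geom$vz, c("DNA", "RNA"))
  thr <- compute_threshold(dna$stack, "otsu")
  objs <- segment_nuclei(dna$stack, thr)
  mask <- object_mask(dna$stack, thr, objs[which.max(objs$voxel_count), ])
  pr <- radial_profile(two, mask, 8)
  expect_lt(channel_anticorrelation(pr, "DNA", "RNA"), 0)
  # symmetric in its arguments
  expect_equal(channel_anticorrelation(pr, "RNA", "DNA"),
               channel_anticorrelation(pr, "DNA", "RNA"))
  # identical channels correlate perfectly
  same <- image_stack(array(c(dna$stack$voxels, dna$stack$voxels),
                            c(dim(dna$stack$voxels), 2)),
                      geom$vx, geom$vz, c("DNA", "RNA"))
  expect_equal(channel_anticorrelation(radial_profile(same, mask, 8)), 1)
  # matches the closed-form Pearson formula
  a <- pr$intensity[, "DNA"]; b <- pr$intensity[, "RNA"]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  want <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(channel_anticorrelation(pr, "DNA", "RNA"), want)
})

test_that("beaded shells score a strictly higher texture CV than smooth shells", {
  score <- function(tex, seed) {
    sp <- nucleus_spec(rep(6, 3), 4.5, "V", dna_bp = 1000 * 34e6,
                       shell_texture = tex, n_chromosomes = 0)
    sc <- scene_spec(c(22, 22, 14), list(sp), voxel_size_xy = 0.55,
                     voxel_size_z = 0.72, rng_seed = seed)
    rr <- render_stack(sc)
    thr <- compute_threshold(rr$stack, "otsu_log")
    objs <- segment_nuclei(rr$stack, thr)
    mask <- object_mask(rr$stack, thr, objs[which.max(objs$voxel_count), ])
    shell_texture_score(rr$stack, mask)
  }
  for (s in 1:3)
    expect_gt(score("beaded", s), score("smooth", s))
  # constant synthetic shell has zero CV
  hollow <- array(FALSE, c(15, 15, 15))
  hollow[3:13, 3:13, 3:13] <- TRUE
  const <- image_stack(array(5, c(15, 15, 15)), 0.5, 0.5)
  expect_equal(shell_texture_score(const, hollow, shell_cut = 0.5), 0)
})
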