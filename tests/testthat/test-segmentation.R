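sphere_render <- render_stack(sharp_sphere_scene())
blurred_render <- render_stack(
  scene_spec(c(60, 60, 30), sharp_sphere_scene()$nuclei, rng_seed = 1))

test_that("thresholding separates well-split modes and honours manual values", {
  v <- array(10, c(12, 12, 6))
  v[4:8, 4:8, 2:5] <- 1000
  st <- image_stack(v, 0.1, 0.13)
  thr <- compute_threshold(st, "otsu")
  expect_gt(thr, 10)
  expect_lt(thr, 1000)
  expect_equal(compute_threshold(st, "manual", manual_value = 50), 50)
  expect_warning(compute_threshold(st, "manual", manual_value = 5000),
                 "outside")
  expect_error(compute_threshold(image_stack(array(3, c(4, 4, 2)),
                                             0.1, 0.13), "otsu"),
               "degenerate")
})

test_that("volume and fluorescence are recovered from a rendered sphere", {
  gt <- blurred_render$ground_truth
  thr <- compute_threshold(blurred_render$stack, "otsu")
  objs <- segment_nuclei(blurred_render$stack, thr)
  expect_equal(nrow(objs), 1)
  expect_equal(objs$volume_um3, gt$volume_um3, tolerance = 0.15)
  expect_equal(objs$total_fluor, gt$total_fluor, tolerance = 0.10)
  expect_false(objs$touches_border)
  # internal consistency of the measurement row
  st <- blurred_render$stack
  expect_equal(objs$volume_um3,
               objs$voxel_count * st$voxel_size_xy^2 * st$voxel_size_z)
})

test_that("two disjoint spheres give two objects and fluorescence is conserved", {
  sp1 <- nucleus_spec(c(2, 2, 1.6), 0.8, "H", dna_bp = 34e6)
  sp2 <- nucleus_spec(c(6, 6, 1.6), 1.0, "H", dna_bp = 68e6)
  sc <- scene_spec(c(80, 80, 24), list(sp1, sp2), rng_seed = 5)
  r <- render_stack(sc)
  thr <- compute_threshold(r$stack, "otsu")
  objs <- segment_nuclei(r$stack, thr)
  expect_equal(nrow(objs), 2)
  expect_lte(sum(objs$total_fluor), sum(r$stack$voxels) + 1e-9)
  # a min-volume filter larger than both removes everything
  expect_equal(nrow(segment_nuclei(r$stack, thr, min_volume_um3 = 100)), 0)
  # empty mask is an empty table, not an error
  expect_equal(nrow(segment_nuclei(r$stack, max(r$stack$voxels) + 1)), 0)
})

test_that("lowering the threshold never shrinks a surviving object", {
  r <- blurred_render
  thr <- compute_threshold(r$stack, "otsu")
  for (f in c(1, 0.7, 0.45, 0.2)) {
    hi <- segment_nuclei(r$stack, thr * f)
    lo <- segment_nuclei(r$stack, thr * f * 0.8)
    expect_gte(max(lo$voxel_count), max(hi$voxel_count))
  }
})

test_that("connected components match an independent flood-fill oracle", {
  set.seed(42)
  cases <- list(list(d = c(16, 16, 16), p = 0.35, conn = 6L),
                list(d = c(16, 16, 16), p = 0.45, conn = 26L),
                list(d = c(32, 32, 32), p = 0.30, conn = 26L))
  for (cs in cases) {
    mask <- array(runif(prod(cs$d)) < cs$p, cs$d)
    got <- label_components_3d(as.logical(mask), as.integer(cs$d), cs$conn)
    want <- flood_fill_labels(mask, cs$conn)
    expect_equal(max(got), max(want))
    expect_true(same_partition(got, want, mask))
  }
})

test_that("heterogeneous populations are fully recovered with the log-domain threshold", {
  specs <- sample_stage_population("gamete", 20, rng_seed = 42)
  sc <- population_scene(specs, rng_seed = 42)
  rr <- render_stack(sc)
  thr <- compute_threshold(rr$stack, "otsu_log")
  objs <- segment_nuclei(rr$stack, thr)
  expect_equal(nrow(objs), 20)
  gt <- rr$ground_truth
  idx <- vapply(seq_len(nrow(objs)), function(i)
    which.min((gt$center_x_um - objs$centroid_x_um[i])^2 +
                (gt$center_y_um - objs$centroid_y_um[i])^2), integer(1))
  rel <- abs(objs$total_fluor - gt$total_fluor[idx]) / gt$total_fluor[idx]
  expect_lt(max(rel), 0.10)
})

test_that("whole-cell measurement subtracts background and checks its inputs", {
  r <- sphere_render
  full <- array(TRUE, dim(r$stack$voxels))
  expect_equal(measure_whole_cell(r$stack, full), sum(r$stack$voxels))
  # mask away from the object: ~0 signal
  m0 <- array(FALSE, dim(r$stack$voxels))
  m0[50:55, 50:55, 25:28] <- TRUE
  expect_lt(abs(measure_whole_cell(r$stack, m0)),
            1e-6 * sum(r$stack$voxels) + 1e-9)
  expect_error(measure_whole_cell(r$stack, m0 & FALSE), "empty")
  expect_error(measure_whole_cell(r$stack, array(TRUE, c(2, 2, 2))),
               "shape")
})

test_that("hole filling restores enclosed cavities only", {
  m <- array(FALSE, c(9, 9, 9))
  m[2:8, 2:8, 2:8] <- TRUE
  m[4:6, 4:6, 4:6] <- FALSE          # enclosed cavity
  filled <- fill_holes_3d(m)
  expect_true(all(filled[4:6, 4:6, 4:6]))
  # carve a corridor from the cavity to the border: no longer a hole
  corridor <- m
  corridor[5, 5, 1:4] <- FALSE
  expect_false(any(fill_holes_3d(corridor)[4:6, 4:6, 4:6]))
})
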