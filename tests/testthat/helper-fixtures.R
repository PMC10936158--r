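# Shared fixture builders and independent oracles.

# A single homogeneous sphere rendered without blur or noise.
sharp_sphere_scene <- function(radius = 1.2, dna_bp = 34e6, seed = 1L) {
  sp <- nucleus_spec(c(3, 3, 2), radius, "H", dna_bp = dna_bp)
  scene_spec(c(60, 60, 30), list(sp), psf_sigma_xy = 0, psf_sigma_z = 0,
             rng_seed = seed)
}

# Render one nucleus of the given architecture and physical volume in its
# own stack (voxel pitch scaled to the nucleus) and return stack, threshold
# and the object's filled mask.
render_one_nucleus <- function(arch, volume_um3, seed, noisy = FALSE,
                               ...) {
  r <- (3 * volume_um3 / (4 * pi))^(1 / 3)
  sp <- nucleus_spec(c(NA, NA, NA), r, arch, dna_bp = 100 * 34e6, ...)
  sc <- population_scene(list(sp),
                         photon_scale = if (noisy) 1 else NULL,
                         rng_seed = seed)
  rr <- render_stack(sc)
  thr <- compute_threshold(rr$stack, "otsu")
  objs <- segment_nuclei(rr$stack, thr)
  obj <- objs[which.max(objs$voxel_count), ]
  list(stack = rr$stack, threshold = thr, object = obj,
       mask = object_mask(rr$stack, thr, obj), truth = rr$ground_truth)
}

# Independent flood-fill connected-components oracle (pure R, depth-first).
flood_fill_labels <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L)
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  labels <- array(0L, d)
  cur <- 0L
  for (start in which(mask)) {
    if (labels[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    labels[start] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ai <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        nb <- ai + offs[r, ]
        if (any(nb < 1L) || any(nb > d)) next
        li <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (mask[li] && labels[li] == 0L) {
          labels[li] <- cur
          stack <- c(stack, li)
        }
      }
    }
  }
  labels
}

# TRUE when two labelings define the same partition of the foreground.
same_partition <- function(a, b, mask) {
  tab <- table(a[mask], b[mask])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Brute-force quartile oracle: sort and linearly interpolate ranks.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Measure a rendered population nucleus-by-nucleus (each in its own stack).
measure_population <- function(stage, n, seed0, noisy = FALSE) {
  specs <- sample_stage_population(stage, n, rng_seed = seed0)
  rows <- lapply(seq_along(specs), function(i) {
    sc <- population_scene(specs[i],
                           photon_scale = if (noisy) 1 else NULL,
                           rng_seed = seed0 + i)
    rr <- render_stack(sc)
    objs <- segment_nuclei(rr$stack, compute_threshold(rr$stack, "otsu"))
    obj <- objs[which.max(objs$voxel_count), ]
    data.frame(volume_um3 = obj$volume_um3, total_fluor = obj$total_fluor,
               true_bp = rr$ground_truth$dna_bp,
               true_fluor = rr$ground_truth$total_fluor)
  })
  do.call(rbind, rows)
}

# A synthetic yeast calibration standard rendered and measured with the
# same fluorescence-per-bp constant as the populations it calibrates.
measure_yeast_standard <- function(n = 20, seed0 = 6000, noisy = FALSE) {
  fl <- vapply(seq_len(n), function(i) {
    sp <- nucleus_spec(c(NA, NA, NA), 0.78, "H", dna_bp = 6e6)
    sc <- population_scene(list(sp),
                           photon_scale = if (noisy) 1 else NULL,
                           rng_seed = seed0 + i)
    rr <- render_stack(sc)
    objs <- segment_nuclei(rr$stack, compute_threshold(rr$stack, "otsu"))
    objs$total_fluor[which.max(objs$voxel_count)]
  }, numeric(1))
  fit_standard("S. cerevisiae", 6e6, 1, fl)
}
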