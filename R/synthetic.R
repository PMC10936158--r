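#' Specification of one synthetic nucleus
#'
#' Describes a Hoechst-like nucleus as an ellipsoid with one of three radial
#' intensity architectures seen in *Allogromia laticollaris* CSH:
#' homogeneous (`"H"`), homogeneous with a small DNA-poor centre (`"HDP"`),
#' and vegetative (`"V"`): a bright peripheral chromatin ring around a
#' DNA-poor, chromosome-bearing core. The rendered object's integrated
#' pre-noise intensity equals `dna_bp * fluor_per_bp` by construction.
#'
#' @param center Physical coordinates (um) of the nucleus centre, length 3
#'   (x, y, z).
#' @param semi_axes Ellipsoid semi-axes in um, length 3. A scalar is
#'   recycled (sphere).
#' @param architecture One of `"H"`, `"HDP"`, `"V"`.
#' @param dna_bp True DNA content in base pairs.
#' @param fluor_per_bp Emitted fluorescence per base pair (F/bp).
#' @param ring_fraction Fraction of the radius occupied by the bright shell,
#'   in (0, 1). Defaults: 0 (H, no shell distinction), 0.55 (HDP), 0.30 (V).
#' @param core_dim_factor Core-to-shell intensity ratio in \[0, 1\].
#'   Defaults: 1 (H), 0.35 (HDP), 0.15 (V).
#' @param n_chromosomes For `"V"` only: number of small bright condensed
#'   bodies placed in the DNA-poor core (default 6; 0 disables).
#' @param shell_texture For `"V"` only: `"smooth"` (latticed-like, default)
#'   or `"beaded"` (shell intensity concentrated in bright spheroids).
#' @return A `nucleus_spec` object.
#' @export
nucleus_spec <- function(center, semi_axes, architecture = c("H", "HDP", "V"),
                         dna_bp, fluor_per_bp = 110000 / 34e6,
                         ring_fraction = NULL, core_dim_factor = NULL,
                         n_chromosomes = NULL, shell_texture = "smooth") {
  architecture <- match.arg(architecture)
  if (length(semi_axes) == 1L) semi_axes <- rep(semi_axes, 3L)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L)
  if (any(semi_axes <= 0)) stop("semi_axes must be positive")
  if (dna_bp <= 0) stop("dna_bp must be positive")
  if (fluor_per_bp <= 0) stop("fluor_per_bp must be positive")
  defaults <- switch(architecture,
    H = list(ring = 0, dim = 1, chrom = 0L),
    HDP = list(ring = 0.55, dim = 0.35, chrom = 0L),
    V = list(ring = 0.30, dim = 0.15, chrom = 6L))
  ring_fraction <- ring_fraction %||% defaults$ring
  core_dim_factor <- core_dim_factor %||% defaults$dim
  n_chromosomes <- n_chromosomes %||% defaults$chrom
  if (ring_fraction < 0 || ring_fraction >= 1)
    stop("ring_fraction must be in [0, 1)")
  if (core_dim_factor < 0 || core_dim_factor > 1)
    stop("core_dim_factor must be in [0, 1]")
  shell_texture <- match.arg(shell_texture, c("smooth", "beaded"))
  structure(
    list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
         architecture = architecture, dna_bp = as.numeric(dna_bp),
         fluor_per_bp = as.numeric(fluor_per_bp),
         ring_fraction = ring_fraction, core_dim_factor = core_dim_factor,
         n_chromosomes = as.integer(n_chromosomes),
         shell_texture = shell_texture),
    class = "nucleus_spec")
}

#' Specification of a synthetic confocal scene
#'
#' @param shape Stack shape in voxels, length 3 (x, y, z).
#' @param nuclei List of [nucleus_spec()] objects.
#' @param voxel_size_xy,voxel_size_z Voxel pitch in um. Defaults 0.1 um in
#'   plane and the 0.13 um z-step typical of the confocal acquisitions
#'   this generator emulates.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigma in um (separable,
#'   anisotropic). 0 disables blur; negative values are rejected.
#' @param photon_scale Photons per fluorescence unit for Poisson shot noise;
#'   `NULL` (default) disables shot noise.
#' @param read_noise_sd Additive Gaussian read noise sd in F; 0 disables.
#' @param background Uniform background level in F per voxel.
#' @param gain Per-stack multiplicative gain factor (emulates smart-gain
#'   variation between acquisitions; default 1).
#' @param rng_seed Integer seed; rendering is bit-reproducible for a fixed
#'   seed.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(shape, nuclei = list(),
                       voxel_size_xy = 0.1, voxel_size_z = 0.13,
                       psf_sigma_xy = 0.1, psf_sigma_z = 0.3,
                       photon_scale = NULL, read_noise_sd = 0,
                       background = 0, gain = 1, rng_seed = 1L) {
  stopifnot(length(shape) == 3L)
  if (any(shape < 1)) stop("stack shape must be positive")
  if (voxel_size_xy <= 0 || voxel_size_z <= 0)
    stop("voxel sizes must be positive")
  if (psf_sigma_xy < 0 || psf_sigma_z < 0)
    stop("PSF sigma must be >= 0 (0 disables blur)")
  if (!is.null(photon_scale) && photon_scale <= 0)
    stop("photon_scale must be positive or NULL")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  if (inherits(nuclei, "nucleus_spec")) nuclei <- list(nuclei)
  structure(
    list(shape = as.integer(shape), nuclei = nuclei,
         voxel_size_xy = voxel_size_xy, voxel_size_z = voxel_size_z,
         psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
         photon_scale = photon_scale, read_noise_sd = read_noise_sd,
         background = background, gain = gain,
         rng_seed = as.integer(rng_seed)),
    class = "scene_spec")
}

# Unnormalized intensity weight field of one nucleus over the voxel grid,
# evaluated with 2x supersampling per axis for partial-volume accuracy.
# Returns a list(idx = linear voxel indices, w = weights).
render_nucleus_weights <- function(spec, shape, vx, vz) {
  cx <- spec$center; ax <- spec$semi_axes
  xs <- axis_coords(shape[1], vx); ys <- axis_coords(shape[2], vx)
  zs <- axis_coords(shape[3], vz)
  ix <- which(abs(xs - cx[1]) <= ax[1] + vx)
  iy <- which(abs(ys - cx[2]) <= ax[2] + vx)
  iz <- which(abs(zs - cx[3]) <= ax[3] + vz)
  if (!length(ix) || !length(iy) || !length(iz))
    stop("nucleus entirely outside stack bounds")
  # chromosome bodies in the V core (positions deterministic given the
  # caller's RNG state)
  chrom <- NULL
  if (spec$architecture == "V" && spec$n_chromosomes > 0) {
    u <- matrix(stats::runif(3 * spec$n_chromosomes, -1, 1),
                ncol = 3)
    u <- u / pmax(sqrt(rowSums(u^2)), 1e-9) *
      stats::runif(spec$n_chromosomes, 0, 0.55)^(1 / 3)
    chrom <- list(pos = sweep(u, 2L, ax * (1 - spec$ring_fraction) * 0.9, "*"),
                  radius = 0.12 * min(ax))
  }
  beads <- NULL
  if (spec$architecture == "V" && spec$shell_texture == "beaded") {
    # ~18 beads of ~0.35 rad angular radius cover roughly half the shell,
    # leaving dim inter-bead gaps that read as a beaded ring
    nb <- 18L
    dirs <- matrix(stats::rnorm(3 * nb), ncol = 3)
    dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-9)
    beads <- list(dirs = dirs, ang = 0.35)
  }
  sub <- c(-0.25, 0.25)
  w <- 0
  for (ox in sub) for (oy in sub) for (oz in sub) {
    gx <- (xs[ix] + ox * vx - cx[1]) / ax[1]
    gy <- (ys[iy] + oy * vx - cx[2]) / ax[2]
    gz <- (zs[iz] + oz * vz - cx[3]) / ax[3]
    rho2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
    rho <- sqrt(rho2)
    inside <- rho <= 1
    core <- rho < (1 - spec$ring_fraction)
    prof <- ifelse(inside, ifelse(core, spec$core_dim_factor, 1), 0)
    if (!is.null(beads)) {
      # bright spheroids on the shell: weight by angular proximity to bead
      # directions, keeping the dim core untouched
      px <- outer(outer(gx, rep(1, length(gy))), rep(1, length(gz)))
      py <- outer(outer(rep(1, length(gx)), gy), rep(1, length(gz)))
      pz <- outer(outer(rep(1, length(gx)), rep(1, length(gy))), gz)
      bump <- 0
      for (b in seq_len(nrow(beads$dirs))) {
        cosang <- (px * beads$dirs[b, 1] + py * beads$dirs[b, 2] +
                     pz * beads$dirs[b, 3]) / pmax(rho, 1e-9)
        bump <- bump + exp(-(acos(pmin(pmax(cosang, -1), 1)) / beads$ang)^2)
      }
      shell <- inside & !core
      prof[shell] <- prof[shell] * (0.4 + bump[shell])
    }
    if (!is.null(chrom)) {
      px <- outer(outer(gx * ax[1], rep(1, length(gy))), rep(1, length(gz)))
      py <- outer(outer(rep(1, length(gx)), gy * ax[2]), rep(1, length(gz)))
      pz <- outer(outer(rep(1, length(gx)), rep(1, length(gy))), gz * ax[3])
      for (b in seq_len(nrow(chrom$pos))) {
        d2 <- (px - chrom$pos[b, 1])^2 + (py - chrom$pos[b, 2])^2 +
          (pz - chrom$pos[b, 3])^2
        prof[d2 <= chrom$radius^2] <- 1.5
      }
    }
    w <- w + prof
  }
  w <- w / 8
  keep <- which(w > 0)
  if (!length(keep)) stop("nucleus entirely outside stack bounds")
  grid <- as.matrix(expand.grid(ix, iy, iz))
  lin <- grid[, 1] + (grid[, 2] - 1) * shape[1] +
    (grid[, 3] - 1) * shape[1] * shape[2]
  list(idx = lin[keep], w = as.numeric(w)[keep])
}

apply_noise <- function(arr, scene) {
  if (!is.null(scene$photon_scale)) {
    lam <- pmax(arr, 0) * scene$photon_scale
    arr[] <- stats::rpois(length(lam), lam) / scene$photon_scale
  }
  if (scene$read_noise_sd > 0)
    arr <- arr + stats::rnorm(length(arr), 0, scene$read_noise_sd)
  pmax(arr, 0)
}

#' Render a synthetic confocal stack with ground truth
#'
#' Nuclei are rasterized as ellipsoids with their architecture's radial
#' intensity profile, scaled so each object's integrated pre-noise intensity
#' equals `dna_bp * fluor_per_bp` exactly, then blurred with a normalized
#' separable Gaussian PSF (intensity-conserving), and finally degraded with
#' Poisson shot noise and Gaussian read noise if enabled. Rendering is
#' bit-reproducible for a fixed `rng_seed`.
#'
#' @param scene A [scene_spec()].
#' @return A list with elements `stack` (an [image_stack()]) and
#'   `ground_truth` (a data frame with one row per nucleus: `nucleus_id`,
#'   `center_x_um`, `center_y_um`, `center_z_um`, `volume_um3`,
#'   `total_fluor`, `dna_bp`, `architecture`).
#' @export
render_stack <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  set.seed(scene$rng_seed)
  shape <- scene$shape
  arr <- array(0, shape)
  gt <- data.frame(nucleus_id = integer(), center_x_um = numeric(),
                   center_y_um = numeric(), center_z_um = numeric(),
                   volume_um3 = numeric(), total_fluor = numeric(),
                   dna_bp = numeric(), architecture = character())
  for (i in seq_along(scene$nuclei)) {
    sp <- scene$nuclei[[i]]
    rw <- render_nucleus_weights(sp, shape, scene$voxel_size_xy,
                                 scene$voxel_size_z)
    total <- sp$dna_bp * sp$fluor_per_bp
    arr[rw$idx] <- arr[rw$idx] + rw$w * (total / sum(rw$w))
    gt <- rbind(gt, data.frame(
      nucleus_id = i, center_x_um = sp$center[1], center_y_um = sp$center[2],
      center_z_um = sp$center[3],
      volume_um3 = 4 / 3 * pi * prod(sp$semi_axes),
      total_fluor = total, dna_bp = sp$dna_bp,
      architecture = sp$architecture))
  }
  arr <- gaussian_blur_3d(arr, scene$psf_sigma_xy, scene$psf_sigma_z,
                          scene$voxel_size_xy, scene$voxel_size_z)
  arr <- arr + scene$background
  arr <- apply_noise(arr, scene)
  arr <- arr * scene$gain
  list(stack = image_stack(arr, scene$voxel_size_xy, scene$voxel_size_z),
       ground_truth = gt)
}

#' Render a synthetic Zerfall cell scene
#'
#' Emulates the three Hoechst-positive structure classes seen in Zerfall
#' cells: constant-width chromatin threads along smooth random paths,
#' small punctate spheres (rendered as Gaussian spots, each carrying a
#' configurable DNA content), and optional dense globular fragments. The
#' total DNA of the scene is partitioned across structures, so fluorescence
#' is conserved through fragmentation by construction.
#'
#' @param thread_width_um True thread width in um (Zerfall chromatin
#'   threads measure 0.25-0.35 um wide on average). A width below twice the in-plane voxel pitch
#'   triggers a warning (under-resolved).
#' @param total_bp Total DNA content of the cell in base pairs.
#' @param n_puncta Number of punctate spheres; each carries
#'   `bp_per_punctum` base pairs.
#' @param bp_per_punctum DNA per punctum in bp; default one haploid genome
#'   complement (34 Mb).
#' @param n_threads Number of thread paths.
#' @param globular_fraction Fraction of `total_bp` placed in globular
#'   fragments (default 0.25; 0 disables).
#' @param n_globular Number of globular fragments.
#' @param fluor_per_bp Fluorescence per base pair.
#' @param shape,voxel_size_xy,voxel_size_z,psf_sigma_xy,psf_sigma_z,photon_scale,read_noise_sd,background
#'   Scene geometry and noise, as in [scene_spec()]. Default in-plane pitch
#'   is 0.05 um so sub-half-micrometre threads are resolved.
#' @param min_separation_um Minimum centre-to-centre distance between
#'   puncta (rejection-sampled placement).
#' @param rng_seed Integer seed.
#' @return A list with `stack` (an [image_stack()]) and `ground_truth`
#'   (one row per structure: `structure_id`, `type`, centre coordinates,
#'   `width_um` for threads, `dna_bp`, `total_fluor`).
#' @export
render_zerfall_scene <- function(thread_width_um = 0.30, total_bp = 300e9,
                                 n_puncta = 20, bp_per_punctum = 34e6,
                                 n_threads = 3, globular_fraction = 0.25,
                                 n_globular = 4,
                                 fluor_per_bp = 110000 / 34e6,
                                 shape = c(160, 160, 12),
                                 voxel_size_xy = 0.05, voxel_size_z = 0.13,
                                 psf_sigma_xy = 0.1, psf_sigma_z = 0.3,
                                 photon_scale = NULL, read_noise_sd = 0,
                                 background = 0,
                                 min_separation_um = 1.2, rng_seed = 1L) {
  if (n_puncta < 0) stop("n_puncta must be >= 0")
  if (thread_width_um <= 0) stop("thread_width_um must be positive")
  if (thread_width_um < 2 * voxel_size_xy)
    warning("thread width ", thread_width_um,
            " um is under-resolved at ", voxel_size_xy, " um pixels")
  set.seed(rng_seed)
  arr <- array(0, shape)
  ext <- c(shape[1] * voxel_size_xy, shape[2] * voxel_size_xy,
           shape[3] * voxel_size_z)
  gt <- list()
  sid <- 0L

  puncta_bp <- n_puncta * bp_per_punctum
  glob_bp <- globular_fraction * total_bp
  thread_bp <- total_bp - puncta_bp - glob_bp
  if (thread_bp < 0)
    stop("total_bp too small for the requested puncta and globular fractions")

  # --- threads: smooth random in-plane paths stamped as constant-width tubes
  if (n_threads > 0 && thread_bp > 0) {
    half_w <- thread_width_um / 2
    rpx <- floor(half_w / voxel_size_xy + 0.5 - 1e-9)
    rpz <- floor(half_w / voxel_size_z + 0.5 - 1e-9)
    offs <- as.matrix(expand.grid(dx = -rpx:rpx, dy = -rpx:rpx, dz = -rpz:rpz))
    keep <- (offs[, 1] * voxel_size_xy)^2 + (offs[, 2] * voxel_size_xy)^2 <=
      half_w^2 & abs(offs[, 3] * voxel_size_z) <= half_w
    offs <- offs[keep, , drop = FALSE]
    thread_mask <- array(FALSE, shape)
    margin <- half_w + 4 * psf_sigma_xy + 0.3
    for (t in seq_len(n_threads)) {
      pos <- c(stats::runif(1, margin, ext[1] - margin),
               stats::runif(1, margin, ext[2] - margin))
      zmid <- ext[3] / 2 + stats::runif(1, -voxel_size_z, voxel_size_z)
      theta <- stats::runif(1, 0, 2 * pi)
      step <- voxel_size_xy / 2
      n_steps <- round(stats::runif(1, 12, 20) / step)
      for (s in seq_len(n_steps)) {
        theta <- theta + stats::rnorm(1, 0, 0.04)
        cand <- pos + step * c(cos(theta), sin(theta))
        if (cand[1] < margin || cand[1] > ext[1] - margin ||
            cand[2] < margin || cand[2] > ext[2] - margin) {
          theta <- theta + pi / 2
          next
        }
        pos <- cand
        ci <- c(ceiling(pos[1] / voxel_size_xy),
                ceiling(pos[2] / voxel_size_xy),
                ceiling(zmid / voxel_size_z))
        vi <- sweep(offs, 2L, ci, "+")
        ok <- vi[, 1] >= 1 & vi[, 1] <= shape[1] &
          vi[, 2] >= 1 & vi[, 2] <= shape[2] &
          vi[, 3] >= 1 & vi[, 3] <= shape[3]
        thread_mask[vi[ok, , drop = FALSE]] <- TRUE
      }
      sid <- sid + 1L
      gt[[sid]] <- data.frame(structure_id = sid, type = "thread",
                              center_x_um = NA_real_, center_y_um = NA_real_,
                              center_z_um = NA_real_,
                              width_um = thread_width_um,
                              dna_bp = thread_bp / n_threads,
                              total_fluor = thread_bp / n_threads *
                                fluor_per_bp)
    }
    nmask <- sum(thread_mask)
    arr[thread_mask] <- arr[thread_mask] +
      thread_bp * fluor_per_bp / nmask
  }

  # --- puncta: Gaussian spots with exact integrated intensity
  if (n_puncta > 0) {
    sig <- 0.15 # um, spot sd before PSF
    centers <- matrix(NA_real_, n_puncta, 3)
    placed <- 0L
    tries <- 0L
    margin <- 3 * sig + 4 * psf_sigma_xy + 0.2
    while (placed < n_puncta && tries < 20000L) {
      tries <- tries + 1L
      cand <- c(stats::runif(1, margin, ext[1] - margin),
                stats::runif(1, margin, ext[2] - margin),
                stats::runif(1, min(margin, ext[3] / 2), max(ext[3] - margin, ext[3] / 2)))
      if (placed > 0) {
        d <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                             cand)^2))
        if (min(d) < min_separation_um) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    if (placed < n_puncta)
      stop("could not place ", n_puncta, " puncta at separation ",
           min_separation_um, " um in this scene")
    xs <- axis_coords(shape[1], voxel_size_xy)
    ys <- axis_coords(shape[2], voxel_size_xy)
    zs <- axis_coords(shape[3], voxel_size_z)
    for (p in seq_len(n_puncta)) {
      ix <- which(abs(xs - centers[p, 1]) <= 4 * sig)
      iy <- which(abs(ys - centers[p, 2]) <= 4 * sig)
      iz <- which(abs(zs - centers[p, 3]) <= 4 * sig)
      gx <- exp(-(xs[ix] - centers[p, 1])^2 / (2 * sig^2))
      gy <- exp(-(ys[iy] - centers[p, 2])^2 / (2 * sig^2))
      gz <- exp(-(zs[iz] - centers[p, 3])^2 / (2 * sig^2))
      w <- outer(outer(gx, gy), gz)
      total <- bp_per_punctum * fluor_per_bp
      arr[ix, iy, iz] <- arr[ix, iy, iz] + w * (total / sum(w))
      sid <- sid + 1L
      gt[[sid]] <- data.frame(structure_id = sid, type = "punctum",
                              center_x_um = centers[p, 1],
                              center_y_um = centers[p, 2],
                              center_z_um = centers[p, 3],
                              width_um = NA_real_, dna_bp = bp_per_punctum,
                              total_fluor = total)
    }
  }

  # --- globular fragments: dense homogeneous ellipsoids
  if (glob_bp > 0 && n_globular > 0) {
    scene_tmp <- scene_spec(shape, voxel_size_xy = voxel_size_xy,
                            voxel_size_z = voxel_size_z, psf_sigma_xy = 0,
                            psf_sigma_z = 0)
    for (g in seq_len(n_globular)) {
      r <- stats::runif(1, 0.5, 0.9)
      ctr <- c(stats::runif(1, r + 1, ext[1] - r - 1),
               stats::runif(1, r + 1, ext[2] - r - 1), ext[3] / 2)
      sp <- nucleus_spec(ctr, r, "H", dna_bp = glob_bp / n_globular,
                         fluor_per_bp = fluor_per_bp)
      rw <- render_nucleus_weights(sp, shape, voxel_size_xy, voxel_size_z)
      total <- sp$dna_bp * fluor_per_bp
      arr[rw$idx] <- arr[rw$idx] + rw$w * (total / sum(rw$w))
      sid <- sid + 1L
      gt[[sid]] <- data.frame(structure_id = sid, type = "globular",
                              center_x_um = ctr[1], center_y_um = ctr[2],
                              center_z_um = ctr[3], width_um = NA_real_,
                              dna_bp = glob_bp / n_globular,
                              total_fluor = total)
    }
  }

  arr <- gaussian_blur_3d(arr, psf_sigma_xy, psf_sigma_z,
                          voxel_size_xy, voxel_size_z)
  arr <- arr + background
  scene_noise <- list(photon_scale = photon_scale,
                      read_noise_sd = read_noise_sd)
  arr <- apply_noise(arr, scene_noise)
  list(stack = image_stack(arr, voxel_size_xy, voxel_size_z),
       ground_truth = if (length(gt)) do.call(rbind, gt) else
         data.frame(structure_id = integer(), type = character(),
                    center_x_um = numeric(), center_y_um = numeric(),
                    center_z_um = numeric(), width_um = numeric(),
                    dna_bp = numeric(), total_fluor = numeric()))
}

#' Packaged life-stage population parameters
#'
#' Medians and quartiles of nuclear volume (um^3), total fluorescence (MF,
#' millions of fluorescence units) and DNA content (C) for each life stage,
#' together with the stage's nuclear architecture label and euploidy, as
#' tabulated for *A. laticollaris* CSH.
#'
#' @return A data frame, one row per stage.
#' @export
stage_params <- function() {
  path <- system.file("extdata", "stage_params.csv", package = "ploidyscope",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# two-piece log-normal deviates matching a printed median and quartiles
# exactly in distribution: below the median the log-sd is fitted to the
# lower quartile, above it to the upper quartile
rlnorm_quartiles <- function(n, med, q25, q75) {
  z75 <- stats::qnorm(0.75)
  s_lo <- log(med / q25) / z75
  s_hi <- log(q75 / med) / z75
  z <- stats::rnorm(n)
  med * exp(z * ifelse(z < 0, s_lo, s_hi))
}

#' Sample a synthetic nuclear population for one life stage
#'
#' Volumes and C-values are drawn from two-piece log-normal distributions
#' whose median and quartiles match the packaged stage parameter table;
#' DNA content is `C * genome_size_bp_1c`. Returned specs have no centres
#' (placement belongs to scene assembly, see [population_scene()]).
#'
#' @param stage Stage label; must match a row of [stage_params()].
#' @param n Number of nuclei.
#' @param rng_seed Integer seed.
#' @param genome_size_bp_1c Haploid genome size in bp (default 34 Mb).
#' @param fluor_per_bp Fluorescence per base pair; the default puts a 1C
#'   nucleus at 0.11 MF, the tabulated gamete median.
#' @return List of [nucleus_spec()] objects with attribute `"truth"`, a
#'   data frame of the sampled volumes and C-values.
#' @export
sample_stage_population <- function(stage, n, rng_seed = 1L,
                                    genome_size_bp_1c = 34e6,
                                    fluor_per_bp = 110000 / 34e6) {
  params <- stage_params()
  row <- params[params$stage == stage, ]
  if (nrow(row) != 1L)
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(params$stage, collapse = ", "))
  if (is.na(row$vol_med))
    stop("stage '", stage, "' has no per-nucleus volume parameters")
  set.seed(rng_seed)
  if (n == 0) {
    out <- list()
    attr(out, "truth") <- data.frame(volume_um3 = numeric(),
                                     c_value = numeric(), dna_bp = numeric())
    return(out)
  }
  vols <- rlnorm_quartiles(n, row$vol_med, row$vol_q25, row$vol_q75)
  cs <- rlnorm_quartiles(n, row$c_med, row$c_q25, row$c_q75)
  arch <- row$render_architecture
  oblong <- row$architecture %in% c("V1", "VL")
  specs <- lapply(seq_len(n), function(i) {
    r <- (3 * vols[i] / (4 * pi))^(1 / 3)
    axes <- if (oblong) r * c(1.35, 1.0, 0.74) else rep(r, 3)
    nucleus_spec(center = c(NA_real_, NA_real_, NA_real_), semi_axes = axes,
                 architecture = arch, dna_bp = cs[i] * genome_size_bp_1c,
                 fluor_per_bp = fluor_per_bp)
  })
  attr(specs, "truth") <- data.frame(volume_um3 = vols, c_value = cs,
                                     dna_bp = cs * genome_size_bp_1c)
  specs
}

#' Assemble sampled nuclei into a renderable scene
#'
#' Places nuclei on a jittered grid with a guaranteed gap between bounding
#' ellipsoids and picks the stack shape to fit. The in-plane voxel size can
#' be set to `"auto"`, which resolves the smallest nucleus with at least
#' `min_voxels_per_radius` voxels per semi-axis (capped below so large
#' stages do not produce enormous stacks).
#'
#' @param specs List of [nucleus_spec()] (centres are overwritten).
#' @param voxel_size_xy In-plane pitch in um, or `"auto"`.
#' @param voxel_size_z Axial step in um, or `"auto"` (sets an isotropic-ish
#'   step scaled from the xy choice, min 0.13).
#' @param gap_um Clearance between neighbouring nuclei and to the border.
#' @param min_voxels_per_radius Resolution target for `"auto"`.
#' @param ... Passed to [scene_spec()] (PSF, noise, seed, ...).
#' @return A `scene_spec`.
#' @export
population_scene <- function(specs, voxel_size_xy = "auto",
                             voxel_size_z = "auto", gap_um = 2,
                             min_voxels_per_radius = 6, ...) {
  if (!length(specs)) stop("no nuclei to place")
  rmax <- vapply(specs, function(s) max(s$semi_axes), numeric(1))
  rmin <- min(vapply(specs, function(s) min(s$semi_axes), numeric(1)))
  if (identical(voxel_size_xy, "auto"))
    voxel_size_xy <- max(0.05, rmin / min_voxels_per_radius)
  if (identical(voxel_size_z, "auto"))
    voxel_size_z <- max(0.13, voxel_size_xy * 1.3)
  pitch <- 2 * max(rmax) + gap_um
  n <- length(specs)
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  zmax <- max(vapply(specs, function(s) s$semi_axes[3], numeric(1)))
  zext <- 2 * zmax + gap_um
  for (i in seq_len(n)) {
    gx <- (i - 1) %% ncol_grid
    gy <- (i - 1) %/% ncol_grid
    specs[[i]]$center <- c(gap_um / 2 + pitch * (gx + 0.5),
                           gap_um / 2 + pitch * (gy + 0.5),
                           zext / 2)
  }
  shape <- c(ceiling((ncol_grid * pitch + gap_um) / voxel_size_xy),
             ceiling((nrow_grid * pitch + gap_um) / voxel_size_xy),
             ceiling(zext / voxel_size_z))
  scene_spec(shape, nuclei = specs, voxel_size_xy = voxel_size_xy,
             voxel_size_z = voxel_size_z, ...)
}
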