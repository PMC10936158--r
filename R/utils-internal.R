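# Internal numerical helpers shared across modules.

# Separable Gaussian blur of a 3D array with sigma given in physical units.
# The 1D kernel matrix applied along each axis is column-normalized, so the
# integrated intensity of the array is conserved exactly (mass near borders
# is redistributed inward rather than lost).
gaussian_blur_3d <- function(arr, sigma_xy_um, sigma_z_um,
                             voxel_size_xy, voxel_size_z) {
  if (sigma_xy_um < 0 || sigma_z_um < 0) stop("PSF sigma must be >= 0")
  d <- dim(arr)
  sx <- sigma_xy_um / voxel_size_xy
  sz <- sigma_z_um / voxel_size_z
  blur_axis <- function(a, axis, sigma_vox) {
    if (sigma_vox < 1e-9) return(a)
    n <- dim(a)[axis]
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-((i - j)^2) / (2 * sigma_vox^2)))
    K <- sweep(K, 2L, colSums(K), "/")
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- K %*% matrix(ap, nrow = n)
    dim(m) <- dp
    aperm(m, order(perm))
  }
  arr <- blur_axis(arr, 1L, sx)
  arr <- blur_axis(arr, 2L, sx)
  arr <- blur_axis(arr, 3L, sz)
  arr
}

# Physical coordinates (um) of voxel centres along each axis. Voxel i spans
# [(i-1)*pitch, i*pitch]; its centre is (i - 0.5)*pitch.
axis_coords <- function(n, pitch) (seq_len(n) - 0.5) * pitch

# 26-neighbourhood local maxima of a 3D array above a threshold.
local_maxima_3d <- function(arr, min_value) {
  d <- dim(arr)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  ismax <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- pad[(2 + dx):(d[1] + 1 + dx),
              (2 + dy):(d[2] + 1 + dy),
              (2 + dz):(d[3] + 1 + dz)]
    ismax <- ismax & (arr >= nb)
  }
  which(ismax & arr >= min_value, arr.ind = TRUE)
}

# Quartile summary with linear interpolation between closest ranks
# (stats::quantile type 7), the package-wide percentile convention.
quartiles <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(q25 = q[1], median = q[2], q75 = q[3])
}
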