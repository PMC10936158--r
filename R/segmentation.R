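#' Compute a stack threshold
#'
#' Interactive analysis of these stacks traditionally sets a threshold per
#' z-stack by hand; here `"otsu"` is the automated stand-in (computed on the pooled voxel histogram of the whole
#' stack) and `"manual"` passes a user value through. `"otsu_log"` runs
#' Otsu on log-transformed intensities, which separates signal from
#' background more robustly when nuclei in one stack differ in brightness
#' by an order of magnitude or more (at the cost of a lower threshold,
#' hence more generous volumes).
#'
#' @param stack An [image_stack()].
#' @param method `"otsu"`, `"otsu_log"` or `"manual"`.
#' @param manual_value Threshold in F, required for `method = "manual"`.
#' @param channel Channel to threshold (default first).
#' @return Threshold in F.
#' @export
compute_threshold <- function(stack, method = c("otsu", "otsu_log",
                                                "manual"),
                              manual_value = NULL, channel = 1L) {
  method <- match.arg(method)
  v <- get_channel(stack, channel)
  rng <- range(v)
  if (method == "manual") {
    if (is.null(manual_value)) stop("manual method requires manual_value")
    if (manual_value < rng[1] || manual_value > rng[2])
      warning("manual threshold ", manual_value,
              " lies outside the stack intensity range [", rng[1], ", ",
              rng[2], "]")
    return(as.numeric(manual_value))
  }
  if (rng[1] == rng[2])
    stop("degenerate histogram: constant stack, Otsu threshold undefined")
  # EBImage's Otsu operates per frame on [0, 1]; pool all voxels into one
  # frame so a single stack-wide threshold comes back, then map it back
  pooled_otsu <- function(x) {
    r <- range(x)
    scaled <- (x - r[1]) / (r[2] - r[1])
    t01 <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1L)),
                         range = c(0, 1))
    r[1] + t01 * (r[2] - r[1])
  }
  if (method == "otsu") return(as.numeric(pooled_otsu(v)))
  eps <- rng[2] * 1e-4
  as.numeric(exp(pooled_otsu(log(v + eps))) - eps)
}

#' Segment 3D nuclei from a thresholded stack
#'
#' Objects are maximal connected components of above-threshold voxels
#' (lattice connectivity 6 or 26; voxel anisotropy does not enter the
#' adjacency). For every object the total fluorescence integrates the *raw*
#' (unthresholded) intensities over the object mask, matching total-
#' fluorescence semantics of summing everything inside the segmented
#' nuclear volume. Objects touching the stack border are flagged and
#' retained; downstream summaries exclude them by default.
#'
#' @param stack An [image_stack()].
#' @param threshold Threshold in F; voxels strictly above it are foreground.
#' @param min_volume_um3 Minimum object volume; smaller objects are
#'   discarded. Default 0.05 um^3, below the smallest biological object
#'   class (0.30 um^3 Zerfall spheres) but above single-voxel noise at the
#'   default pitch.
#' @param connectivity 6 or 26 (default).
#' @param measure_dilation_um Physical radius (um) by which each object's
#'   mask is expanded for the fluorescence integral only, capturing
#'   PSF-spread signal just outside the thresholded boundary; voxels
#'   claimed by several objects go to the nearest one, so fluorescence is
#'   never double-counted. Volume and voxel_count always come from the
#'   undilated mask. Default 0.45 um (about 1.5 axial PSF sigma at the
#'   synthetic defaults); 0 disables.
#' @param fill_holes Fill interior cavities of the thresholded mask before
#'   labelling (default TRUE). Vegetative nuclei threshold as bright rings
#'   around a sub-threshold DNA-poor centre; the nuclear volume and the
#'   fluorescence integral must include that centre (and any condensed
#'   chromosome bodies within it), so cavities are restored to the object.
#' @param channel Channel to segment (measurements also use this channel).
#' @return Data frame with one row per object: `label`, `voxel_count`,
#'   `volume_um3`, `total_fluor`, `mean_fluor`, `centroid_x_um`,
#'   `centroid_y_um`, `centroid_z_um`, `touches_border`.
#' @export
segment_nuclei <- function(stack, threshold, min_volume_um3 = 0.05,
                           connectivity = 26L, measure_dilation_um = 0.45,
                           fill_holes = TRUE, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (min_volume_um3 < 0) stop("min_volume_um3 must be >= 0")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  v <- get_channel(stack, channel)
  d <- dim(v)
  mask <- v > threshold
  if (fill_holes && any(mask)) mask <- fill_holes_3d(mask)
  empty <- data.frame(label = integer(), voxel_count = integer(),
                      volume_um3 = numeric(), total_fluor = numeric(),
                      mean_fluor = numeric(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(), centroid_z_um = numeric(),
                      touches_border = logical())
  if (!any(mask)) return(empty)
  labels <- label_components_3d(as.logical(mask), as.integer(d),
                                as.integer(connectivity))
  fg <- which(labels > 0L)
  lab <- labels[fg]
  idx <- arrayInd(fg, d)
  vals <- v[fg]
  vvol <- voxel_volume(stack)

  counts <- tabulate(lab)
  total <- vapply(split(vals, lab), sum, numeric(1))
  if (measure_dilation_um > 0) {
    # expand each object's integration region by a physical radius; a
    # contested voxel is credited to the nearest object only
    nlab <- length(counts)
    bestd <- array(Inf, d)
    bestl <- array(0L, d)
    for (l in seq_len(nlab)) {
      dl <- edt_3d(labels != l, as.integer(d), stack$voxel_size_xy,
                   stack$voxel_size_xy, stack$voxel_size_z)
      upd <- labels == 0L & dl > 0 & dl <= measure_dilation_um & dl < bestd
      bestd[upd] <- dl[upd]
      bestl[upd] <- l
    }
    halo <- which(bestl > 0L)
    if (length(halo)) {
      add <- vapply(split(v[halo],
                          factor(bestl[halo], levels = seq_len(nlab))),
                    sum, numeric(1))
      total <- total + add
    }
  }
  cx <- vapply(split(idx[, 1], lab), mean, numeric(1))
  cy <- vapply(split(idx[, 2], lab), mean, numeric(1))
  cz <- vapply(split(idx[, 3], lab), mean, numeric(1))
  border <- idx[, 1] == 1L | idx[, 1] == d[1] |
    idx[, 2] == 1L | idx[, 2] == d[2] |
    idx[, 3] == 1L | idx[, 3] == d[3]
  touches <- vapply(split(border, lab), any, logical(1))

  out <- data.frame(
    label = seq_along(counts),
    voxel_count = counts,
    volume_um3 = counts * vvol,
    total_fluor = as.numeric(total),
    mean_fluor = as.numeric(total) / counts,
    centroid_x_um = (as.numeric(cx) - 0.5) * stack$voxel_size_xy,
    centroid_y_um = (as.numeric(cy) - 0.5) * stack$voxel_size_xy,
    centroid_z_um = (as.numeric(cz) - 0.5) * stack$voxel_size_z,
    touches_border = as.logical(touches))
  out <- out[out$volume_um3 >= min_volume_um3, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Voxel mask of one segmented object
#'
#' Recomputes the component labelling and returns the logical mask of the
#' object whose centroid row is supplied, for use with per-object
#' operations such as [radial_profile()].
#'
#' @param stack An [image_stack()].
#' @param threshold Segmentation threshold.
#' @param object One row of the [segment_nuclei()] output.
#' @param connectivity 6 or 26.
#' @param channel Channel that was segmented.
#' @param fill_holes Fill interior cavities of the mask (default TRUE).
#'   Nuclei with a DNA-poor centre threshold as hollow shells; the radial
#'   profile needs the full nuclear volume, core included.
#' @return Logical 3D array.
#' @export
object_mask <- function(stack, threshold, object, connectivity = 26L,
                        channel = 1L, fill_holes = TRUE) {
  v <- get_channel(stack, channel)
  d <- dim(v)
  mask <- v > threshold
  if (fill_holes && any(mask)) mask <- fill_holes_3d(mask)
  labels <- label_components_3d(as.logical(mask), as.integer(d),
                                as.integer(connectivity))
  if (!is.null(object$label) && object$label >= 1 &&
      object$label <= max(labels))
    return(labels == object$label)
  # fallback when the label is unavailable: nearest component to the
  # recorded centroid
  ci <- c(round(object$centroid_x_um / stack$voxel_size_xy + 0.5),
          round(object$centroid_y_um / stack$voxel_size_xy + 0.5),
          round(object$centroid_z_um / stack$voxel_size_z + 0.5))
  ci <- pmin(pmax(ci, 1L), d)
  lab <- labels[ci[1], ci[2], ci[3]]
  if (lab == 0L) {
    fg <- which(labels > 0L)
    idx <- arrayInd(fg, d)
    dist2 <- (idx[, 1] - ci[1])^2 + (idx[, 2] - ci[2])^2 +
      (idx[, 3] - ci[3])^2
    lab <- labels[fg[which.min(dist2)]]
  }
  labels == lab
}

#' Fill interior cavities of a 3D mask
#'
#' Background components (6-connected) that do not reach the array border
#' are interior holes and are set to foreground.
#'
#' @param mask Logical 3D array.
#' @return Logical 3D array with holes filled.
#' @export
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  bg <- label_components_3d(!mask, as.integer(d), 6L)
  nbg <- max(bg)
  if (nbg == 0L) return(mask)
  border_labs <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                          bg[, , 1], bg[, , d[3]]))
  border_labs <- border_labs[border_labs > 0L]
  hole <- bg > 0L & !(bg %in% border_labs)
  dim(hole) <- d
  mask | hole
}

#' Integrated fluorescence of a whole cell
#'
#' Sums raw intensities inside a cell mask and subtracts a background
#' estimate: the median intensity outside the mask times the number of
#' voxels inside. Used for whole-Zerfall-cell DNA content, where the signal
#' is dispersed through the cytoplasm rather than confined to nuclei.
#'
#' @param stack An [image_stack()].
#' @param cell_mask Logical array, same shape as the stack's channel.
#' @param channel Channel to measure.
#' @return Background-corrected total fluorescence in F.
#' @export
measure_whole_cell <- function(stack, cell_mask, channel = 1L) {
  v <- get_channel(stack, channel)
  if (!identical(dim(cell_mask), dim(v)))
    stop("cell_mask shape does not match the stack")
  n_in <- sum(cell_mask)
  if (n_in == 0) stop("empty cell mask")
  bg <- if (n_in == length(v)) 0 else stats::median(v[!cell_mask])
  sum(v[cell_mask]) - bg * n_in
}
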