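#' Construct an image stack
#'
#' A 3D (or multi-channel 4D) grid of fluorescence intensities with physical
#' voxel sizes. Intensities are in arbitrary fluorescence units (F); volumes
#' derived from the stack are in cubic micrometres.
#'
#' @param voxels Numeric array, either `x * y * z` (single channel) or
#'   `x * y * z * channel`. All values must be non-negative and finite.
#' @param voxel_size_xy In-plane voxel pitch in micrometres.
#' @param voxel_size_z Axial step in micrometres (a typical confocal
#'   z-step is 0.13 um).
#' @param channels Character vector of channel labels, e.g. `c("DNA", "RNA")`.
#'   Length must match the 4th dimension (1 for a 3D array).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size_xy, voxel_size_z,
                        channels = "DNA") {
  if (!is.array(voxels) || !(length(dim(voxels)) %in% c(3L, 4L)))
    stop("`voxels` must be a 3D or 4D numeric array")
  storage.mode(voxels) <- "double"
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("stack intensities must be finite")
  if (any(voxels < 0))
    stop("stack intensities must be non-negative")
  if (!is.numeric(voxel_size_xy) || voxel_size_xy <= 0 ||
      !is.numeric(voxel_size_z) || voxel_size_z <= 0)
    stop("voxel sizes must be positive")
  nch <- if (length(dim(voxels)) == 4L) dim(voxels)[4] else 1L
  if (length(channels) != nch)
    stop("length(channels) must match the number of channels (", nch, ")")
  structure(
    list(voxels = voxels,
         voxel_size_xy = as.numeric(voxel_size_xy),
         voxel_size_z = as.numeric(voxel_size_z),
         channels = as.character(channels)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<image_stack> ", paste(d[1:3], collapse = " x "),
      " voxels, ", length(x$channels), " channel(s): ",
      paste(x$channels, collapse = ", "), "\n",
      "  voxel ", x$voxel_size_xy, " x ", x$voxel_size_xy, " x ",
      x$voxel_size_z, " um\n", sep = "")
  invisible(x)
}

#' Extract one channel of a stack as a 3D array
#'
#' @param stack An `image_stack`.
#' @param channel Channel label or index; defaults to the first channel.
#' @return 3D numeric array.
#' @export
get_channel <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    idx <- match(channel, stack$channels)
    if (is.na(idx)) stop("no channel named '", channel, "'; available: ",
                         paste(stack$channels, collapse = ", "))
  } else idx <- as.integer(channel)
  v <- stack$voxels
  if (length(dim(v)) == 3L) {
    if (idx != 1L) stop("stack has a single channel")
    return(v)
  }
  v[, , , idx, drop = TRUE]
}

#' Physical volume of one voxel in cubic micrometres
#' @param stack An `image_stack`.
#' @return Scalar, `voxel_size_xy^2 * voxel_size_z`.
#' @export
voxel_volume <- function(stack) {
  stack$voxel_size_xy^2 * stack$voxel_size_z
}

#' Write a stack to multi-page TIFF with a YAML sidecar
#'
#' One TIFF page per z-plane (channels interleaved within a page set per z),
#' stored as 32-bit float. The sidecar records voxel sizes, channel labels
#' and any extra scene metadata so that [read_stack()] can reconstruct the
#' object losslessly.
#'
#' @param stack An `image_stack`.
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.yaml` unless `sidecar_path` is given.
#' @param sidecar_path Optional explicit sidecar path.
#' @param metadata Named list of extra fields (seed, scene parameters, ...)
#'   stored verbatim in the sidecar.
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(stack, path, sidecar_path = NULL, metadata = list()) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(sidecar_path)) sidecar_path <- paste0(path, ".yaml")
  v <- stack$voxels
  if (length(dim(v)) == 3L) dim(v) <- c(dim(v), 1L)
  d <- dim(v)
  # integer-valued stacks that fit in 16 bits are stored losslessly as
  # uint16; everything else goes through float storage on [0, 1], divided
  # by a power of two so the rescaling is mantissa-exact
  mx <- max(v)
  integer_mode <- mx <= 65535 && all(v == round(v))
  scale <- if (integer_mode || mx <= 1) 1 else 2^ceiling(log2(mx))
  denom <- if (integer_mode) 65535 else scale
  pages <- vector("list", d[3] * d[4])
  k <- 0L
  for (z in seq_len(d[3])) for (ch in seq_len(d[4])) {
    k <- k + 1L
    pages[[k]] <- v[, , z, ch] / denom
  }
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (integer_mode) 16L else 32L,
                  reduce = FALSE)
  side <- c(list(
    shape = as.integer(d),
    voxel_size_xy_um = stack$voxel_size_xy,
    voxel_size_z_um = stack$voxel_size_z,
    storage = if (integer_mode) "uint16" else "float32",
    intensity_scale = scale,
    channels = as.list(stack$channels)), metadata)
  yaml::write_yaml(side, sidecar_path)
  invisible(sidecar_path)
}

#' Read a stack written by [write_stack()]
#'
#' Voxel sizes come from the YAML sidecar; without a sidecar (or explicit
#' `voxel_size_*` arguments) the read fails, because volumes computed from a
#' stack with unknown voxel size would be meaningless.
#'
#' @param path TIFF path.
#' @param sidecar_path Sidecar path; defaults to `<path>.yaml`.
#' @param voxel_size_xy,voxel_size_z Optional overrides used when no sidecar
#'   exists.
#' @return An `image_stack`; the sidecar's extra metadata is attached as
#'   attribute `"metadata"`.
#' @export
read_stack <- function(path, sidecar_path = NULL,
                       voxel_size_xy = NULL, voxel_size_z = NULL) {
  if (!file.exists(path)) stop("no such TIFF: ", path)
  if (is.null(sidecar_path)) sidecar_path <- paste0(path, ".yaml")
  side <- NULL
  if (file.exists(sidecar_path)) side <- yaml::read_yaml(sidecar_path)
  vx <- voxel_size_xy %||% side$voxel_size_xy_um
  vz <- voxel_size_z %||% side$voxel_size_z_um
  if (is.null(vx) || is.null(vz))
    stop("voxel sizes unavailable for ", path,
         ": supply a sidecar or voxel_size_xy/voxel_size_z")
  integer_mode <- identical(side$storage, "uint16")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = integer_mode)
  if (!is.list(pages)) pages <- list(pages)
  channels <- if (!is.null(side$channels)) unlist(side$channels) else "DNA"
  nch <- length(channels)
  nz <- length(pages) / nch
  if (nz != round(nz)) stop("page count not divisible by channel count in ", path)
  d1 <- dim(pages[[1]])
  arr <- array(0, c(d1[1], d1[2], nz, nch))
  scale <- if (integer_mode) 1 else side$intensity_scale %||% 1
  k <- 0L
  for (z in seq_len(nz)) for (ch in seq_len(nch)) {
    k <- k + 1L
    arr[, , z, ch] <- pages[[k]] * scale
  }
  if (nch == 1L) dim(arr) <- dim(arr)[1:3]
  out <- image_stack(arr, vx, vz, channels)
  extra <- side[setdiff(names(side),
                        c("shape", "voxel_size_xy_um", "voxel_size_z_um",
                          "storage", "intensity_scale", "channels"))]
  attr(out, "metadata") <- extra
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
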