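#' Multi-channel 3D image stack
#'
#' Container for a confocal z-stack: a 4-D voxel array indexed
#' `(channel, z, y, x)` with physical voxel size in micrometres per axis,
#' named channels, and a declared coverslip end. Slice `z = 1` is the
#' coverslip-proximal section when `coverslip_end = "low_z"` (the default).
#'
#' @param voxels numeric 4-D array, dim `(n_channels, nz, ny, nx)`, or a 3-D
#'   array which is promoted to a single channel. Intensities must be finite
#'   and non-negative.
#' @param voxel_size_zyx numeric length-3, micrometres per voxel along
#'   `(z, y, x)`; all components positive.
#' @param channel_names character vector naming the channels, e.g.
#'   `c("dna", "gfp")`.
#' @param coverslip_end `"low_z"` or `"high_z"`: which z extreme is nearest
#'   the coverslip.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size_zyx, channel_names,
                        coverslip_end = "low_z") {
  if (length(dim(voxels)) == 3L) {
    dim(voxels) <- c(1L, dim(voxels))
  }
  if (length(dim(voxels)) != 4L) {
    stop("`voxels` must be a 3-D or 4-D array")
  }
  voxel_size_zyx <- as.numeric(voxel_size_zyx)
  if (length(voxel_size_zyx) != 3L || any(!is.finite(voxel_size_zyx)) ||
      any(voxel_size_zyx <= 0)) {
    stop("`voxel_size_zyx` must be 3 positive numbers (um)")
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(voxels)[1L]) {
    stop(sprintf("channel_names has length %d but stack has %d channel(s)",
                 length(channel_names), dim(voxels)[1L]))
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  coverslip_end <- match.arg(coverslip_end, c("low_z", "high_z"))
  if (any(!is.finite(voxels))) stop("voxel intensities must be finite")
  if (any(voxels < 0)) stop("voxel intensities must be non-negative")
  structure(
    list(voxels = voxels, voxel_size_zyx = voxel_size_zyx,
         channel_names = channel_names, coverslip_end = coverslip_end),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d channel(s) [%s], %d x %d x %d (z,y,x)\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4]))
  cat(sprintf("  voxel size (um, z/y/x): %s; coverslip end: %s\n",
              paste(format(x$voxel_size_zyx), collapse = " / "),
              x$coverslip_end))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

# shape of the spatial grid (nz, ny, nx)
stack_shape <- function(stack) dim(stack$voxels)[-1L]

#' Extract one channel of an image stack as a 3-D array
#'
#' @param stack an [image_stack()].
#' @param channel channel name or 1-based index.
#' @return 3-D numeric array, dim `(nz, ny, nx)`.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    i <- match(channel, stack$channel_names)
    if (is.na(i)) {
      stop(sprintf("channel '%s' not found (available: %s)", channel,
                   paste(stack$channel_names, collapse = ", ")))
    }
  } else {
    i <- as.integer(channel)
    if (i < 1L || i > dim(stack$voxels)[1L]) stop("channel index out of range")
  }
  arr <- stack$voxels[i, , , , drop = FALSE]
  dim(arr) <- dim(stack$voxels)[-1L]
  arr
}

#' Integer-labelled 3D segmentation map
#'
#' Shares the spatial geometry of its source stack; `0` is background and the
#' positive labels are the contiguous set `1..K`.
#'
#' @param labels integer 3-D array, dim `(nz, ny, nx)`, values >= 0.
#' @param voxel_size_zyx micrometres per voxel along `(z, y, x)`.
#' @param compact if `TRUE` (default) relabel positive ids to `1..K`
#'   preserving order of first appearance.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, voxel_size_zyx, compact = TRUE) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3-D array")
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L)) {
    stop("labels must be non-negative integers")
  }
  voxel_size_zyx <- as.numeric(voxel_size_zyx)
  if (length(voxel_size_zyx) != 3L || any(voxel_size_zyx <= 0)) {
    stop("`voxel_size_zyx` must be 3 positive numbers (um)")
  }
  if (compact) {
    ids <- sort(unique(labels[labels > 0L]))
    if (length(ids) && !identical(ids, seq_along(ids))) {
      lut <- integer(max(ids) + 1L)
      lut[ids + 1L] <- seq_along(ids)
      labels[] <- ifelse(labels > 0L, lut[labels + 1L], 0L)
    }
  }
  structure(list(labels = labels, voxel_size_zyx = voxel_size_zyx),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_map: %d x %d x %d (z,y,x), %d label(s)\n",
              d[1], d[2], d[3], n_labels(x)))
  invisible(x)
}

#' Number of positive labels in a label map
#' @param lmap a [label_map()].
#' @return integer count of distinct positive labels.
#' @export
n_labels <- function(lmap) {
  stopifnot(inherits(lmap, "label_map"))
  m <- max(lmap$labels)
  if (m == 0L) 0L else length(unique(lmap$labels[lmap$labels > 0L]))
}

#' Physical voxel volume of a stack or label map
#' @param x an [image_stack()] or [label_map()], or a length-3 voxel size.
#' @return voxel volume in cubic micrometres.
#' @export
voxel_volume <- function(x) {
  vs <- if (is.numeric(x)) x else x$voxel_size_zyx
  prod(vs)
}
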