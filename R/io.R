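# Stack / label-map / record IO on top of the TIFF codec and CSV.

.stack_desc <- function(stack) {
  jsonlite::toJSON(list(
    format = "gutcount-stack", version = 1L, axes = "CZYX",
    shape = dim(stack$voxels), voxel_size_zyx = stack$voxel_size_zyx,
    channel_names = stack$channel_names, coverslip_end = stack$coverslip_end
  ), auto_unbox = FALSE, digits = NA)
}

.parse_desc <- function(description) {
  if (is.null(description)) return(NULL)
  meta <- tryCatch(jsonlite::fromJSON(description), error = function(e) NULL)
  if (is.null(meta) || is.null(meta$format)) return(NULL)
  meta
}

#' Write an image stack to a multi-page TIFF
#'
#' Planes are stored channel-first (all z of channel 1, then channel 2, ...),
#' 16-bit by default; geometry (axes, shape, voxel size, channel names,
#' coverslip end) goes into the ImageDescription as JSON so that
#' [read_stack()] round-trips losslessly without side-car files.
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @param bits bits per sample (8, 16 or 32). Intensities are rounded; values
#'   outside the representable range raise an error.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      k <- k + 1L
      pg <- stack$voxels[ch, z, , ]
      dim(pg) <- d[3:4]
      pages[[k]] <- round(pg)
    }
  }
  tiff_write(pages, path, bits = bits, description = .stack_desc(stack))
}

#' Read an image stack from a multi-page TIFF
#'
#' Geometry comes from the gutcount JSON block in the ImageDescription when
#' present; otherwise it must be supplied. The reader never guesses a voxel
#' size: a file without embedded geometry and without `voxel_size_override`
#' is an error.
#'
#' @param path TIFF path.
#' @param voxel_size_override length-3 numeric `(z, y, x)` in micrometres;
#'   required when the file carries no gutcount geometry, and takes
#'   precedence when it does.
#' @param channel_names channel names; for files without embedded geometry
#'   the page count must be a multiple of `length(channel_names)` (planes
#'   assumed channel-first). Default for plain files: single channel `"ch1"`.
#' @param coverslip_end `"low_z"` or `"high_z"`; default from metadata, else
#'   `"low_z"`.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, voxel_size_override = NULL, channel_names = NULL,
                       coverslip_end = NULL) {
  tf <- tiff_read(path)
  if (!length(tf$pages)) stop("TIFF contains no pages")
  meta <- .parse_desc(tf$description)
  if (!is.null(meta) && identical(meta$format, "gutcount-stack")) {
    vs <- if (!is.null(voxel_size_override)) voxel_size_override else
      as.numeric(meta$voxel_size_zyx)
    cn <- if (!is.null(channel_names)) channel_names else
      as.character(meta$channel_names)
    ce <- if (!is.null(coverslip_end)) coverslip_end else
      as.character(meta$coverslip_end)
  } else {
    if (is.null(voxel_size_override)) {
      stop("TIFF carries no voxel-size metadata; supply voxel_size_override")
    }
    vs <- voxel_size_override
    cn <- if (!is.null(channel_names)) channel_names else "ch1"
    ce <- if (!is.null(coverslip_end)) coverslip_end else "low_z"
  }
  nc <- length(cn)
  npage <- length(tf$pages)
  if (npage %% nc != 0L) {
    stop(sprintf("%d page(s) not divisible by %d channel(s)", npage, nc))
  }
  nz <- npage %/% nc
  ny <- nrow(tf$pages[[1L]]); nx <- ncol(tf$pages[[1L]])
  vox <- array(0, dim = c(nc, nz, ny, nx))
  k <- 0L
  for (ch in seq_len(nc)) {
    for (z in seq_len(nz)) {
      k <- k + 1L
      vox[ch, z, , ] <- tf$pages[[k]]
    }
  }
  image_stack(vox, vs, cn, ce)
}

#' Write a label map as a single-channel integer TIFF
#'
#' @param lmap a [label_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(lmap, path) {
  stopifnot(inherits(lmap, "label_map"))
  bits <- if (max(lmap$labels) > 65535L) 32L else 16L
  d <- dim(lmap$labels)
  pages <- lapply(seq_len(d[1]), function(z) {
    pg <- lmap$labels[z, , ]
    dim(pg) <- d[2:3]
    pg
  })
  desc <- jsonlite::toJSON(list(
    format = "gutcount-labels", version = 1L, axes = "ZYX",
    shape = d, voxel_size_zyx = lmap$voxel_size_zyx
  ), auto_unbox = FALSE, digits = NA)
  tiff_write(pages, path, bits = bits, description = desc)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path TIFF path.
#' @param voxel_size_override length-3 numeric, required if the file carries
#'   no gutcount geometry.
#' @return a [label_map()].
#' @export
read_label_map <- function(path, voxel_size_override = NULL) {
  tf <- tiff_read(path)
  meta <- .parse_desc(tf$description)
  if (!is.null(meta) && identical(meta$format, "gutcount-labels")) {
    vs <- if (!is.null(voxel_size_override)) voxel_size_override else
      as.numeric(meta$voxel_size_zyx)
  } else if (!is.null(voxel_size_override)) {
    vs <- voxel_size_override
  } else {
    stop("TIFF carries no voxel-size metadata; supply voxel_size_override")
  }
  nz <- length(tf$pages)
  ny <- nrow(tf$pages[[1L]]); nx <- ncol(tf$pages[[1L]])
  arr <- array(0L, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- as.integer(tf$pages[[z]])
  label_map(arr, vs, compact = FALSE)
}

# canonical nucleus-record column order; mean-intensity columns slot in
# after volume_um3
.record_fixed_cols <- c("image_id", "id", "z_um", "y_um", "x_um", "volume_um3")
.record_tail_cols <- c("size_class", "clone", "depth_kept")

#' Empty nucleus-record table
#'
#' @param channel_names channels for which `mean_<channel>` columns exist.
#' @return zero-row data frame with the canonical record columns.
#' @export
empty_records <- function(channel_names = character()) {
  cols <- c(.record_fixed_cols,
            if (length(channel_names)) paste0("mean_", channel_names),
            .record_tail_cols)
  df <- as.data.frame(
    c(list(image_id = character(), id = integer(), z_um = numeric(),
           y_um = numeric(), x_um = numeric(), volume_um3 = numeric()),
      stats::setNames(rep(list(numeric()), length(channel_names)),
                      paste0("mean_", channel_names)),
      list(size_class = character(), clone = logical(),
           depth_kept = logical()))
  )
  df[, cols, drop = FALSE]
}

#' Write per-nucleus records to CSV
#'
#' One row per nucleus; stable column order with units in header names
#' (`volume_um3`, `*_um`). An empty record set yields a header-only file.
#'
#' @param records data frame of nucleus records (see [measure_nuclei()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) && length(unique(records$image_id)) > 1L) {
    stop("records span multiple image_ids; write one file per image")
  }
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read per-nucleus records from CSV
#'
#' @param path CSV path written by [write_records()].
#' @return data frame of nucleus records.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("clone", "depth_kept"), names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}
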