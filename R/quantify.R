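# Per-image tissue readouts: cell counts, clone ratios, marker-positive cell
# ratios, positive-volume / total-volume ratios, and punctate spot counts.
# Undefined ratios (zero denominator) propagate as NA, never as 0.

#' Count cells, clone cells and small clone cells
#'
#' Counts run over depth-kept records only (`depth_kept` must be filled; use
#' [filter_depth()], or set every record's flag to `TRUE` when no depth
#' restriction applies).
#'
#' @param records classified, depth-filtered nucleus records.
#' @return list: `n_total`, `n_clone`, `n_small_clone`.
#' @export
count_cells <- function(records) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) {
    return(list(n_total = 0L, n_clone = 0L, n_small_clone = 0L))
  }
  if (any(is.na(records$depth_kept)) || any(is.na(records$clone)) ||
      any(is.na(records$size_class))) {
    stop("records must be classified and depth-filtered before counting")
  }
  kept <- records[records$depth_kept, , drop = FALSE]
  list(n_total = nrow(kept),
       n_clone = sum(kept$clone),
       n_small_clone = sum(kept$clone & kept$size_class == "small"))
}

#' Positive-volume to tissue-volume ratio
#'
#' The "GFP-positive area / total area" style readout, computed in 3D voxel
#' volume: the fraction of tissue voxels in which the positive channel
#' exceeds its threshold. The tissue mask comes from thresholding
#' `tissue_channel`, or covers the whole domain when `tissue_channel` is
#' `"all"`. Voxel volume cancels, so the ratio is invariant to uniform
#' voxel-size rescaling.
#'
#' @param stack an [image_stack()].
#' @param positive_channel channel quantified (e.g. GFP, Caspase, Elav).
#' @param tissue_channel channel defining the tissue mask, or `"all"`.
#' @param positive_threshold intensity cut for the positive channel
#'   (strictly `>`), or `"auto"` for Otsu.
#' @param tissue_threshold intensity cut for the tissue channel, or
#'   `"auto"`.
#' @param projection_2d if `TRUE`, compute on the maximum z-projection
#'   instead of the 3D volume (comparison mode, not the default).
#' @return the ratio in `[0, 1]`, or `NA` (with a warning) when the tissue
#'   mask is empty.
#' @export
positive_volume_ratio <- function(stack, positive_channel,
                                  tissue_channel = "all",
                                  positive_threshold = "auto",
                                  tissue_threshold = "auto",
                                  projection_2d = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  pos <- get_channel(stack, positive_channel)
  if (identical(tissue_channel, "all")) {
    tis_mask <- array(TRUE, dim = dim(pos))
  } else {
    tis <- get_channel(stack, tissue_channel)
    tthr <- if (identical(tissue_threshold, "auto")) {
      otsu_threshold(as.numeric(tis))
    } else tissue_threshold
    tis_mask <- tis > tthr
  }
  pthr <- if (identical(positive_threshold, "auto")) {
    otsu_threshold(as.numeric(pos))
  } else positive_threshold
  pos_mask <- pos > pthr
  if (projection_2d) {
    tis_mask <- apply(tis_mask, c(2, 3), any)
    pos_mask <- apply(pos_mask, c(2, 3), any)
  }
  denom <- sum(tis_mask)
  if (denom == 0L) {
    warning("empty tissue mask; positive-volume ratio is undefined")
    return(NA_real_)
  }
  sum(pos_mask & tis_mask) / denom
}

#' Marker-positive cell ratio
#'
#' The "Dl-positive (or Pros-positive) cells / total cells" readout: the
#' fraction of depth-kept nuclei whose mean intensity in `marker_channel`
#' is `>=` the threshold.
#'
#' @param records measured, depth-filtered nucleus records.
#' @param marker_channel marker channel name.
#' @param threshold intensity cut on the per-nucleus mean (`>=`), or
#'   `"auto"` for the exhaustive Otsu optimum of the means.
#' @return the ratio in `[0, 1]`, or `NA` when no cells remain.
#' @export
marker_cell_ratio <- function(records, marker_channel, threshold) {
  stopifnot(is.data.frame(records))
  col <- paste0("mean_", marker_channel)
  if (nrow(records) && !col %in% names(records)) {
    stop(sprintf("records carry no '%s' column", col))
  }
  if (nrow(records) && any(is.na(records$depth_kept))) {
    stop("records must be depth-filtered before computing marker ratios")
  }
  kept <- records[records$depth_kept %in% TRUE, , drop = FALSE]
  if (!nrow(kept)) return(NA_real_)
  thr <- if (identical(threshold, "auto")) {
    optimize_threshold_1d(kept[[col]], "otsu_1d")
  } else threshold
  mean(kept[[col]] >= thr)
}

#' Count punctate marker spots
#'
#' The PH3-style mitotic count: connected components (6-connectivity) of the
#' thresholded channel whose volume lies within `[min_volume_um3,
#' max_volume_um3]`. Spots merged below resolution count once — a documented
#' limitation of component counting without watershed.
#'
#' @param stack an [image_stack()].
#' @param channel punctate marker channel.
#' @param threshold intensity cut (strictly `>`), or `"auto"` for Otsu.
#' @param min_volume_um3,max_volume_um3 admissible spot volume interval.
#' @return integer spot count.
#' @export
count_spots <- function(stack, channel, threshold = "auto",
                        min_volume_um3 = 0.5, max_volume_um3 = Inf) {
  stopifnot(inherits(stack, "image_stack"))
  if (min_volume_um3 > max_volume_um3) {
    stop("min_volume_um3 must not exceed max_volume_um3")
  }
  ch <- get_channel(stack, channel)
  if (identical(threshold, "auto")) {
    if (length(unique(as.numeric(ch))) < 2L) return(0L)
    threshold <- otsu_threshold(as.numeric(ch))
  }
  mask <- ch > threshold
  if (!any(mask)) return(0L)
  lab <- .cpp_label3d(as.logical(mask), as.integer(dim(ch)))
  counts <- tabulate(lab[lab > 0L], nbins = max(lab))
  vv <- voxel_volume(stack)
  sum(counts * vv >= min_volume_um3 & counts * vv <= max_volume_um3)
}

#' Summarise one image into tissue-level metrics
#'
#' @param records classified, depth-filtered nucleus records.
#' @param stack the source [image_stack()].
#' @param image_id identifier for the summary row.
#' @param positive_channel channel for the positive-volume ratio (e.g.
#'   `"gfp"`); `NULL` skips it.
#' @param tissue_channel tissue-mask channel for the ratio, or `"all"`.
#' @param marker_channel per-cell marker channel; `NULL` skips the
#'   marker-cell ratio.
#' @param marker_threshold threshold for the marker-cell ratio.
#' @param spot_channel punctate channel; `NULL` skips spot counting.
#' @param spot_params list with `threshold`, `min_volume_um3`,
#'   `max_volume_um3` for [count_spots()].
#' @return one-row data frame: image_id, n_total, n_clone, clone_cell_ratio,
#'   n_small_clone, marker_cell_ratio, positive_volume_ratio, n_spots.
#' @export
summarize_image <- function(records, stack, image_id = "image",
                            positive_channel = "gfp",
                            tissue_channel = "all",
                            marker_channel = NULL,
                            marker_threshold = "auto",
                            spot_channel = NULL,
                            spot_params = list(threshold = "auto",
                                               min_volume_um3 = 0.5,
                                               max_volume_um3 = Inf)) {
  counts <- count_cells(records)
  ccr <- if (counts$n_total > 0L) counts$n_clone / counts$n_total else
    NA_real_
  mcr <- if (!is.null(marker_channel)) {
    marker_cell_ratio(records, marker_channel, marker_threshold)
  } else NA_real_
  pvr <- if (!is.null(positive_channel)) {
    positive_volume_ratio(stack, positive_channel, tissue_channel)
  } else NA_real_
  nsp <- if (!is.null(spot_channel)) {
    count_spots(stack, spot_channel, spot_params$threshold,
                spot_params$min_volume_um3, spot_params$max_volume_um3)
  } else NA_integer_
  data.frame(image_id = image_id,
             n_total = counts$n_total,
             n_clone = counts$n_clone,
             clone_cell_ratio = ccr,
             n_small_clone = counts$n_small_clone,
             marker_cell_ratio = mcr,
             positive_volume_ratio = pvr,
             n_spots = nsp)
}
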