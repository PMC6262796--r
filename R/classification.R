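# Size / clone / depth classification of measured nuclei.
#
# Size classes follow the ~90 um^3 volume split between small progenitor-like
# (ISC/EB) and big enterocyte-like nuclei, with the cut optimised per image;
# clone membership follows the per-nucleus mean green intensity, likewise
# optimised per image. Depth filtering keeps only nuclei in the half of the
# tissue closest to the coverslip, to avoid depth-dependent signal loss.

#' Classifier parameters
#'
#' @param volume_threshold_um3 numeric cut (um^3) or `"auto"` for per-image
#'   optimisation. When optimisation fails, or returns a cut outside the
#'   range of the observed volumes, the fixed fallback of 90 um^3 is used.
#' @param clone_intensity_threshold numeric cut or `"auto"` (per-image Otsu
#'   on the per-nucleus mean green intensities).
#' @param clone_fallback optional numeric cut used when automatic clone
#'   optimisation fails (fewer than 2 distinct means); `NULL` propagates the
#'   error.
#' @param auto_method_size method for the automatic volume cut:
#'   `"kmeans2"` (two-means on log-volume, default — robust to the long
#'   big-cell tail) or `"otsu_1d"`.
#' @param depth_filter whether downstream counting restricts to the
#'   coverslip-proximal half (on by default for gut analyses).
#' @return validated `classifier_params` object.
#' @export
classifier_params <- function(volume_threshold_um3 = "auto",
                              clone_intensity_threshold = "auto",
                              clone_fallback = NULL,
                              auto_method_size = c("kmeans2", "otsu_1d"),
                              depth_filter = TRUE) {
  auto_method_size <- match.arg(auto_method_size)
  chk <- function(x, nm) {
    if (!(identical(x, "auto") ||
          (is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0))) {
      stop(sprintf("%s must be a positive number or \"auto\"", nm))
    }
  }
  chk(volume_threshold_um3, "volume_threshold_um3")
  chk(clone_intensity_threshold, "clone_intensity_threshold")
  structure(list(volume_threshold_um3 = volume_threshold_um3,
                 clone_intensity_threshold = clone_intensity_threshold,
                 clone_fallback = clone_fallback,
                 auto_method_size = auto_method_size,
                 depth_filter = isTRUE(depth_filter)),
            class = "classifier_params")
}

#' Optimise a 1-D two-class threshold
#'
#' `"otsu_1d"` exhaustively maximises inter-class variance over all midpoints
#' between consecutive sorted distinct values. `"kmeans2"` runs 1-D two-means
#' with deterministic initialisation at the minimum and maximum and returns
#' the midpoint of the converged cluster means.
#'
#' @param values numeric vector with at least 2 distinct finite values.
#' @param method `"kmeans2"` or `"otsu_1d"`.
#' @return the threshold; classification convention is `value >= threshold`
#'   for the upper class.
#' @export
optimize_threshold_1d <- function(values, method = c("kmeans2", "otsu_1d")) {
  method <- match.arg(method)
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L) {
    stop(paste("need at least 2 distinct values to optimise a threshold;",
               "use the fixed fallback instead"))
  }
  if (method == "kmeans2") {
    c1 <- min(v); c2 <- max(v)
    for (it in 1:100) {
      up <- abs(v - c2) < abs(v - c1)   # ties go to the lower cluster
      n1 <- mean(v[!up]); n2 <- mean(v[up])
      if (isTRUE(all.equal(c(c1, c2), c(n1, n2)))) break
      c1 <- n1; c2 <- n2
    }
    (c1 + c2) / 2
  } else {
    s <- sort(unique(v))
    cuts <- (s[-1] + s[-length(s)]) / 2
    n <- length(v)
    best <- -Inf; best_cut <- cuts[1]
    for (cut in cuts) {
      lo <- v[v < cut]; hi <- v[v >= cut]
      w0 <- length(lo) / n
      sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
      if (sb > best) { best <- sb; best_cut <- cut }
    }
    best_cut
  }
}

#' Classify nuclei into small and big by volume
#'
#' `size_class` is `"big"` when `volume_um3 >= threshold`, else `"small"`
#' (tie classifies as big). With `"auto"`, the cut is optimised on this
#' image's volumes — two-means on log-volume by default — and exponentiated
#' back; when optimisation fails or lands outside the observed volume range,
#' the fixed 90 um^3 fallback applies.
#'
#' @param records nucleus records (from [measure_nuclei()]).
#' @param params a [classifier_params()].
#' @return list: `records` with `size_class` filled, and
#'   `volume_threshold_um3` (the cut used, auditable per image).
#' @export
classify_size <- function(records, params = classifier_params()) {
  stopifnot(is.data.frame(records))
  fallback <- 90.0
  if (!nrow(records)) {
    thr <- if (identical(params$volume_threshold_um3, "auto")) fallback else
      params$volume_threshold_um3
    return(list(records = records, volume_threshold_um3 = thr))
  }
  vols <- records$volume_um3
  if (identical(params$volume_threshold_um3, "auto")) {
    thr <- tryCatch({
      t_raw <- if (params$auto_method_size == "kmeans2") {
        exp(optimize_threshold_1d(log(vols), "kmeans2"))
      } else {
        optimize_threshold_1d(vols, "otsu_1d")
      }
      if (t_raw < min(vols) || t_raw > max(vols)) fallback else t_raw
    }, error = function(e) fallback)
  } else {
    thr <- params$volume_threshold_um3
  }
  records$size_class <- ifelse(vols >= thr, "big", "small")
  list(records = records, volume_threshold_um3 = thr)
}

#' Classify nuclei as clone-positive or not by mean green intensity
#'
#' `clone` is `TRUE` when the nucleus' mean intensity in `green_channel` is
#' `>=` the threshold (tie counts as clone-positive). With `"auto"`, the cut
#' is the exhaustive Otsu optimum of this image's per-nucleus means; with
#' fewer than 2 distinct means the optimisation is impossible and
#' `clone_fallback` is used, or an error raised when none is set.
#'
#' @param records nucleus records carrying a `mean_<green_channel>` column.
#' @param green_channel clone/GFP channel name (default `"gfp"`).
#' @param params a [classifier_params()].
#' @return list: `records` with `clone` filled, and
#'   `clone_intensity_threshold` (the cut used).
#' @export
classify_clone <- function(records, green_channel = "gfp",
                           params = classifier_params()) {
  stopifnot(is.data.frame(records))
  col <- paste0("mean_", green_channel)
  if (!nrow(records)) {
    thr <- if (identical(params$clone_intensity_threshold, "auto"))
      NA_real_ else params$clone_intensity_threshold
    return(list(records = records, clone_intensity_threshold = thr))
  }
  if (!col %in% names(records)) {
    stop(sprintf("records carry no '%s' column", col))
  }
  means <- records[[col]]
  if (identical(params$clone_intensity_threshold, "auto")) {
    thr <- tryCatch(optimize_threshold_1d(means, "otsu_1d"),
                    error = function(e) {
                      if (is.null(params$clone_fallback)) stop(e)
                      params$clone_fallback
                    })
  } else {
    thr <- params$clone_intensity_threshold
  }
  records$clone <- means >= thr
  list(records = records, clone_intensity_threshold = thr)
}

#' Depth-filter nuclei to the coverslip-proximal half
#'
#' A nucleus is kept when its physical centroid z lies in the half-open
#' interval covering the half of the z extent nearest the coverslip:
#' `z < Z/2` for `coverslip_end = "low_z"`, `z >= Z/2` for `"high_z"`, with
#' `Z` the physical z extent (`nz * voxel_z`). The midplane itself is
#' excluded for `"low_z"` (half-open rule). The filter only sets
#' `depth_kept`; rows are never dropped, so keeps + discards = total.
#'
#' @param records nucleus records with physical centroids.
#' @param stack the source [image_stack()] (declares z extent and
#'   coverslip end).
#' @return `records` with `depth_kept` filled.
#' @export
filter_depth <- function(records, stack) {
  stopifnot(is.data.frame(records), inherits(stack, "image_stack"))
  if (is.null(stack$coverslip_end) || is.na(stack$coverslip_end)) {
    stop("stack does not declare coverslip_end")
  }
  if (!nrow(records)) {
    records$depth_kept <- logical(0)
    return(records)
  }
  z_extent <- dim(stack$voxels)[2L] * stack$voxel_size_zyx[1L]
  half <- z_extent / 2
  records$depth_kept <- if (stack$coverslip_end == "low_z") {
    records$z_um < half
  } else {
    records$z_um >= half
  }
  records
}
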