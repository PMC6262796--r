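# Nuclear segmentation: fluorescence threshold, 3D connected components,
# distance-transform watershed to separate touching nuclei, and per-nucleus
# measurement. The distance transform is computed in physical micrometres so
# the anisotropic z axis (1 um sections vs sub-um xy) is respected.

#' Segmentation parameters
#'
#' @param threshold intensity cutoff for the nuclear channel, or `"auto"` for
#'   Otsu's criterion on the channel histogram. A supplied numeric value
#'   always wins over the automatic choice. The mask uses a strict `>` at the
#'   boundary.
#' @param min_volume_um3 debris filter: labels smaller than this (um^3) are
#'   removed after splitting. Default 5, well below the small-nucleus
#'   population.
#' @param watershed_enabled if `FALSE`, connected components are returned
#'   unsplit.
#' @param h_depth h-maxima suppression depth for seed finding, in um of the
#'   distance map: shallower peaks than this merge into their neighbour.
#' @param min_seed_separation_um minimum pairwise distance between accepted
#'   seeds within one connected component.
#' @param exclude_border drop labels touching the image border (off by
#'   default; no edge-exclusion rule is imposed).
#' @return validated `segmentation_params` object.
#' @export
segmentation_params <- function(threshold = "auto", min_volume_um3 = 5.0,
                                watershed_enabled = TRUE, h_depth = 1.0,
                                min_seed_separation_um = 2.0,
                                exclude_border = FALSE) {
  if (!(identical(threshold, "auto") ||
        (is.numeric(threshold) && length(threshold) == 1L &&
         is.finite(threshold)))) {
    stop("threshold must be a single number or \"auto\"")
  }
  if (min_volume_um3 < 0) stop("min_volume_um3 must be >= 0")
  if (h_depth < 0) stop("h_depth must be >= 0")
  if (min_seed_separation_um < 0) stop("min_seed_separation_um must be >= 0")
  structure(list(threshold = threshold,
                 min_volume_um3 = as.numeric(min_volume_um3),
                 watershed_enabled = isTRUE(watershed_enabled),
                 h_depth = as.numeric(h_depth),
                 min_seed_separation_um = as.numeric(min_seed_separation_um),
                 exclude_border = isTRUE(exclude_border)),
            class = "segmentation_params")
}

#' Otsu threshold of an intensity sample
#'
#' Maximises inter-class variance over a binned histogram; returns the cut
#' value (midpoint of the best bin edge). Errors on constant input, where no
#' threshold is definable.
#'
#' @param x numeric vector of intensities.
#' @param n_bins histogram resolution.
#' @return threshold value; foreground is `x > threshold`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (!length(x) || rng[1] == rng[2]) {
    stop("cannot compute an Otsu threshold of a constant image")
  }
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w0c <- w0[-n_bins]; muc <- mu[-n_bins]
  denom <- w0c * (1 - w0c)
  sigma_b <- ifelse(denom > 0, (mu_t * w0c - muc)^2 / denom, -Inf)
  k <- which.max(sigma_b)
  br[k + 1L]   # upper edge of the best background bin
}

#' Threshold the nuclear channel into a foreground mask
#'
#' @param stack an [image_stack()].
#' @param channel nuclear channel name or index (default `"dna"`).
#' @param params a [segmentation_params()]; `threshold` may be numeric or
#'   `"auto"` (Otsu).
#' @return list: `mask` (logical 3-D array, `TRUE` where intensity strictly
#'   exceeds the cut) and `threshold` (the value used — auditable when
#'   chosen automatically).
#' @export
threshold_nuclei <- function(stack, channel = "dna",
                             params = segmentation_params()) {
  ch <- get_channel(stack, channel)
  thr <- if (identical(params$threshold, "auto")) {
    otsu_threshold(as.numeric(ch))
  } else {
    params$threshold
  }
  list(mask = ch > thr, threshold = thr)
}

# distance in um between two (z,y,x) voxel-index triples
.vox_dist_um <- function(a, b, vs) {
  sqrt(sum(((a - b) * vs)^2))
}

#' Split touching nuclei by seeded watershed on the distance transform
#'
#' The Euclidean distance transform of the mask is computed in physical
#' micrometres (anisotropy-aware). Seeds are the h-maxima of the distance
#' map (suppression depth `h_depth`); within each connected component, seeds
#' closer than `min_seed_separation_um` to an already accepted (deeper) seed
#' are merged into it. The watershed floods the negated distance map
#' restricted to the mask, so labels partition the mask exactly; components
#' with a single seed pass through unchanged. Labels smaller than
#' `min_volume_um3` are removed and ids compacted.
#'
#' @param mask logical 3-D array (from [threshold_nuclei()]).
#' @param voxel_size_zyx micrometres per voxel `(z, y, x)`.
#' @param params a [segmentation_params()].
#' @return a [label_map()].
#' @export
split_touching <- function(mask, voxel_size_zyx,
                           params = segmentation_params()) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  shape <- dim(mask)
  vs <- as.numeric(voxel_size_zyx)
  vv <- prod(vs)
  empty <- label_map(array(0L, dim = shape), vs, compact = FALSE)
  if (!any(mask)) return(empty)

  comp <- array(.cpp_label3d(as.logical(mask), as.integer(shape)),
                dim = shape)

  if (!params$watershed_enabled) {
    lab <- comp
  } else {
    dist <- .cpp_edt(as.logical(mask), as.integer(shape), vs)
    h <- max(params$h_depth, 1e-6)
    rec <- .cpp_reconstruct(pmax(dist - h, 0), dist, as.integer(shape))
    # the h-maxima are where the residual saturates at h: peaks of
    # prominence below h leave a residual equal to that (smaller)
    # prominence and must not seed
    seed_mask <- (dist - rec) >= h - 1e-6 & as.logical(mask)
    seeds <- .cpp_label3d(seed_mask, as.integer(shape))

    # per-seed summary: peak distance, argmax voxel, parent component
    seed_ids <- sort(unique(seeds[seeds > 0L]))
    keep_seed <- logical(length(seed_ids))
    if (length(seed_ids)) {
      info <- lapply(seed_ids, function(s) {
        w <- which(seeds == s)
        best <- w[which.max(dist[w])]
        ai <- arrayInd(best, shape)[1, ]
        list(peak = dist[best], at = ai, comp = comp[best])
      })
      # within each component, greedy acceptance deepest-first
      comps <- vapply(info, `[[`, 0, "comp")
      peaks <- vapply(info, `[[`, 0, "peak")
      for (cid in unique(comps)) {
        members <- which(comps == cid)
        members <- members[order(-peaks[members], seed_ids[members])]
        accepted <- integer(0)
        for (m in members) {
          ok <- TRUE
          for (a in accepted) {
            if (.vox_dist_um(info[[m]]$at, info[[a]]$at, vs) <
                params$min_seed_separation_um) { ok <- FALSE; break }
          }
          if (ok) accepted <- c(accepted, m)
        }
        keep_seed[accepted] <- TRUE
      }
      drop_ids <- seed_ids[!keep_seed]
      if (length(drop_ids)) seeds[seeds %in% drop_ids] <- 0L
    }
    # safeguard: any component without a surviving seed becomes one label,
    # seeded at its distance-map argmax
    has_seed <- unique(comp[seeds > 0L])
    orphan <- setdiff(unique(comp[comp > 0L]), has_seed)
    if (length(orphan)) {
      base <- max(seeds)
      for (i in seq_along(orphan)) {
        w <- which(comp == orphan[i])
        seeds[w[which.max(dist[w])]] <- base + i
      }
    }
    lab <- array(.cpp_watershed(-dist, as.integer(seeds),
                                as.logical(mask), as.integer(shape)),
                 dim = shape)
  }

  # debris filter + optional border exclusion, then compaction
  if (max(lab) > 0L) {
    counts <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(counts > 0L & counts * vv < params$min_volume_um3)
    if (params$exclude_border) {
      border <- array(FALSE, dim = shape)
      border[c(1, shape[1]), , ] <- TRUE
      border[, c(1, shape[2]), ] <- TRUE
      border[, , c(1, shape[3])] <- TRUE
      drop <- union(drop, unique(lab[border & lab > 0L]))
    }
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  label_map(lab, vs, compact = TRUE)
}

#' Measure segmented nuclei
#'
#' One record per positive label: physical centroid (um, voxel-centre
#' convention), volume (voxel count x voxel volume), and the per-channel
#' arithmetic mean intensity over the label's voxels. Classification fields
#' (`size_class`, `clone`, `depth_kept`) are left unset (`NA`).
#'
#' @param lmap a [label_map()].
#' @param stack the [image_stack()] the labels were derived from; must share
#'   `(z, y, x)` shape and voxel size.
#' @param image_id identifier stored with each record.
#' @return data frame of nucleus records (columns `image_id, id, z_um, y_um,
#'   x_um, volume_um3, mean_<channel>..., size_class, clone, depth_kept`).
#' @export
measure_nuclei <- function(lmap, stack, image_id = "image") {
  stopifnot(inherits(lmap, "label_map"), inherits(stack, "image_stack"))
  if (!identical(dim(lmap$labels), dim(stack$voxels)[-1L])) {
    stop("label map and stack have different (z,y,x) shapes")
  }
  if (max(abs(lmap$voxel_size_zyx - stack$voxel_size_zyx)) > 1e-9) {
    stop("label map and stack have different voxel sizes")
  }
  vs <- stack$voxel_size_zyx
  lab <- lmap$labels
  w <- which(lab > 0L)
  if (!length(w)) return(empty_records(stack$channel_names))
  ids <- lab[w]
  uid <- sort(unique(ids))
  f <- factor(ids, levels = uid)
  counts <- as.integer(table(f))
  ai <- arrayInd(w, dim(lab))
  z_um <- tapply(.vox_center(ai[, 1], vs[1]), f, mean)
  y_um <- tapply(.vox_center(ai[, 2], vs[2]), f, mean)
  x_um <- tapply(.vox_center(ai[, 3], vs[3]), f, mean)
  df <- data.frame(image_id = image_id, id = uid,
                   z_um = as.numeric(z_um), y_um = as.numeric(y_um),
                   x_um = as.numeric(x_um),
                   volume_um3 = counts * voxel_volume(vs))
  for (ch in stack$channel_names) {
    v <- get_channel(stack, ch)[w]
    df[[paste0("mean_", ch)]] <- as.numeric(tapply(v, f, mean))
  }
  df$size_class <- NA_character_
  df$clone <- NA
  df$depth_kept <- NA
  df
}

#' Segment a stack end to end
#'
#' Convenience composition of [threshold_nuclei()], [split_touching()] and
#' [measure_nuclei()].
#'
#' @inheritParams threshold_nuclei
#' @param image_id identifier stored with each record.
#' @return list: `labels` ([label_map()]), `records` (data frame),
#'   `threshold` (the nuclear threshold used).
#' @export
segment_stack <- function(stack, channel = "dna",
                          params = segmentation_params(),
                          image_id = "image") {
  th <- threshold_nuclei(stack, channel, params)
  lmap <- split_touching(th$mask, stack$voxel_size_zyx, params)
  records <- measure_nuclei(lmap, stack, image_id = image_id)
  list(labels = lmap, records = records, threshold = th$threshold)
}
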