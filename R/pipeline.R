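# End-to-end orchestration: segment -> measure -> classify (size, clone) ->
# depth filter -> summarise, per image, then group statistics across
# genotypes. Every automatically chosen threshold is logged per image, since
# per-image optimisation makes them analysis parameters that must be
# auditable.

.as_seg_params <- function(x) {
  if (inherits(x, "segmentation_params")) x else
    do.call(segmentation_params, as.list(x))
}
.as_cls_params <- function(x) {
  if (inherits(x, "classifier_params")) x else
    do.call(classifier_params, as.list(x))
}

#' Build a run configuration
#'
#' @param images data frame with columns `path` (TIFF file) and `group`
#'   (genotype label), optionally `image_id` (defaults to the file stem).
#' @param channels list of channel roles: `dna` (nuclear), `clone` (green),
#'   optional `marker`, `tissue` (channel for the tissue mask of the
#'   positive-volume ratio, or `"all"`), optional `spot`.
#' @param segmentation a [segmentation_params()] or argument list.
#' @param classification a [classifier_params()] or argument list.
#' @param marker_threshold threshold for the marker-cell ratio.
#' @param spot_params list for [count_spots()].
#' @param depth_filter_ratios apply the depth restriction to area-ratio
#'   metrics too (default `FALSE`: it applies to cell counts only).
#' @param stats_mode statistics mode for [run_compare()].
#' @param seed RNG seed recorded with the run.
#' @return object of class `run_config`.
#' @export
run_config <- function(images,
                       channels = list(dna = "dna", clone = "gfp",
                                       tissue = "all"),
                       segmentation = segmentation_params(),
                       classification = classifier_params(),
                       marker_threshold = "auto",
                       spot_params = list(threshold = "auto",
                                          min_volume_um3 = 0.5,
                                          max_volume_um3 = Inf),
                       depth_filter_ratios = FALSE,
                       stats_mode = "auto",
                       seed = 1L) {
  images <- as.data.frame(images)
  if (nrow(images)) {
    if (!all(c("path", "group") %in% names(images))) {
      stop("images must have 'path' and 'group' columns")
    }
    if (any(!nzchar(as.character(images$group)))) {
      stop("group labels must be non-empty")
    }
    if (is.null(images$image_id)) {
      images$image_id <- tools::file_path_sans_ext(basename(images$path))
    }
  }
  if (is.null(channels$dna)) stop("channels$dna is required")
  structure(list(images = images, channels = channels,
                 segmentation = .as_seg_params(segmentation),
                 classification = .as_cls_params(classification),
                 marker_threshold = marker_threshold,
                 spot_params = spot_params,
                 depth_filter_ratios = isTRUE(depth_filter_ratios),
                 stats_mode = stats_mode, seed = as.integer(seed)),
            class = "run_config")
}

#' Quantify one stack through the full pipeline
#'
#' Stage order: threshold + watershed segmentation, measurement, size
#' classification, clone classification, depth filtering, then counting —
#' depth restriction is applied before all counts.
#'
#' @param stack an [image_stack()].
#' @param config a [run_config()].
#' @param image_id identifier for outputs.
#' @return list: `records`, `summary` (one-row data frame), `labels`,
#'   `thresholds` (named list of every threshold used on this image).
#' @export
quantify_stack <- function(stack, config, image_id = "image") {
  ch <- config$channels
  seg <- segment_stack(stack, channel = ch$dna,
                       params = config$segmentation, image_id = image_id)
  records <- seg$records
  cs <- classify_size(records, config$classification)
  records <- cs$records
  thresholds <- list(nuclear_intensity = seg$threshold,
                     volume_um3 = cs$volume_threshold_um3)
  if (!is.null(ch$clone) && ch$clone %in% stack$channel_names) {
    cc <- classify_clone(records, green_channel = ch$clone,
                         params = config$classification)
    records <- cc$records
    thresholds$clone_intensity <- cc$clone_intensity_threshold
  } else {
    records$clone <- FALSE
  }
  if (config$classification$depth_filter) {
    records <- filter_depth(records, stack)
  } else if (nrow(records)) {
    records$depth_kept <- TRUE
  } else {
    records$depth_kept <- logical(0)
  }
  summary <- summarize_image(
    records, stack, image_id = image_id,
    positive_channel = if (!is.null(ch$clone) &&
                           ch$clone %in% stack$channel_names) ch$clone,
    tissue_channel = if (is.null(ch$tissue)) "all" else ch$tissue,
    marker_channel = if (!is.null(ch$marker) &&
                         ch$marker %in% stack$channel_names) ch$marker,
    marker_threshold = config$marker_threshold,
    spot_channel = if (!is.null(ch$spot) &&
                       ch$spot %in% stack$channel_names) ch$spot,
    spot_params = config$spot_params)
  list(records = records, summary = summary, labels = seg$labels,
       thresholds = thresholds)
}

#' Run the quantification pipeline over a manifest of images
#'
#' Processes every image in `config$images`; a failure in one image is
#' reported (image id + stage message) and the remaining images are still
#' processed. Deterministic given config + seed. When `out_dir` is given,
#' writes `summaries.csv`, one `nuclei_<image_id>.csv` per image, a
#' `run_log.txt` listing every per-image threshold, and a frozen copy of the
#' resolved configuration (`run_config.yaml`) for provenance.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list: `summaries` (data frame with `group` column), `records`
#'   (named list of per-image record data frames), `thresholds` (per-image
#'   named lists), `failures` (named character vector of error messages).
#' @export
run_quantify <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  imgs <- config$images
  summaries <- list()
  records <- list()
  thresholds <- list()
  failures <- character(0)
  log_lines <- character(0)
  for (i in seq_len(nrow(imgs))) {
    id <- as.character(imgs$image_id[i])
    res <- tryCatch({
      stack <- read_stack(as.character(imgs$path[i]))
      quantify_stack(stack, config, image_id = id)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      log_lines <- c(log_lines,
                     sprintf("image %s: FAILED (%s)", id, failures[id]))
      next
    }
    s <- res$summary
    s$group <- as.character(imgs$group[i])
    summaries[[id]] <- s
    records[[id]] <- res$records
    thresholds[[id]] <- res$thresholds
    log_lines <- c(log_lines, sprintf(
      "image %s: thresholds %s", id,
      paste(sprintf("%s=%.6g", names(res$thresholds),
                    unlist(res$thresholds)), collapse = ", ")))
  }
  summaries <- if (length(summaries)) {
    do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  } else {
    data.frame(image_id = character(0), n_total = integer(0),
               n_clone = integer(0), clone_cell_ratio = numeric(0),
               n_small_clone = integer(0), marker_cell_ratio = numeric(0),
               positive_volume_ratio = numeric(0), n_spots = integer(0),
               group = character(0))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
    for (id in names(records)) {
      write_records(records[[id]],
                    file.path(out_dir, paste0("nuclei_", id, ".csv")))
    }
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    frozen <- list(
      images = lapply(seq_len(nrow(imgs)), function(i) as.list(imgs[i, ])),
      channels = config$channels,
      segmentation = unclass(config$segmentation),
      classification = unclass(config$classification),
      marker_threshold = config$marker_threshold,
      depth_filter_ratios = config$depth_filter_ratios,
      stats_mode = config$stats_mode, seed = config$seed)
    yaml::write_yaml(frozen, file.path(out_dir, "run_config.yaml"))
  }
  list(summaries = summaries, records = records, thresholds = thresholds,
       failures = failures)
}

#' Compare a summary metric across genotype groups
#'
#' @param summaries data frame from [run_quantify()] (or path to its
#'   `summaries.csv`); must carry `group` and the metric column.
#' @param metric summary column to compare, e.g. `"clone_cell_ratio"`.
#' @param mode `"auto"`, `"parametric"` or `"nonparametric"`.
#' @param out_dir if given, writes `compare_<metric>.json` and a plain-text
#'   table `compare_<metric>.txt`.
#' @return a [group_compare()] result.
#' @export
run_compare <- function(summaries, metric, mode = "auto", out_dir = NULL) {
  if (is.character(summaries)) {
    summaries <- utils::read.csv(summaries, stringsAsFactors = FALSE)
  }
  metrics <- setdiff(names(summaries), c("image_id", "group"))
  if (!metric %in% metrics) {
    stop(sprintf("unknown metric '%s'; available: %s", metric,
                 paste(metrics, collapse = ", ")))
  }
  if (!"group" %in% names(summaries)) stop("summaries carry no 'group'")
  groups <- split(summaries[[metric]], summaries$group)
  if (length(groups) < 2L) stop("need at least 2 groups to compare")
  cmp <- group_compare(groups, mode = mode, metric = metric)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(metric = cmp$metric, mode = cmp$mode, note = cmp$note,
           summary = cmp$summary,
           omnibus = cmp$omnibus, omnibus_stars = cmp$omnibus_stars,
           pairwise = as.data.frame(cmp$pairwise),
           pairwise_stars = as.data.frame(cmp$pairwise_stars)),
      file.path(out_dir, paste0("compare_", metric, ".json")),
      auto_unbox = TRUE, digits = NA, na = "null")
    txt <- utils::capture.output(print(cmp))
    writeLines(txt, file.path(out_dir, paste0("compare_", metric, ".txt")))
  }
  cmp
}
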