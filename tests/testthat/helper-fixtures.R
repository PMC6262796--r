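# Shared fixtures: all test data is generated in code at test time.

# small, fast generator configuration for unit tests
small_params <- function(...) {
  args <- list(...)
  defaults <- list(shape_zyx = c(20L, 80L, 80L),
                   voxel_size_zyx = c(1.0, 0.31, 0.31),
                   n_small = 4L, n_big = 2L, seed = 42L)
  do.call(simulation_params, utils::modifyList(defaults, args))
}

# clean forward model: no blur, no noise -> exact intensities
clean_params <- function(...) {
  small_params(blur_sigma_zyx = c(0, 0, 0), noise_model = "none", ...)
}

# a digital ball mask centred in a 3-D array, radius in um
ball_mask <- function(shape, vs, center_um, radius_um) {
  g <- expand.grid(z = seq_len(shape[1]), y = seq_len(shape[2]),
                   x = seq_len(shape[3]))
  d2 <- ((g$z - 0.5) * vs[1] - center_um[1])^2 +
    ((g$y - 0.5) * vs[2] - center_um[2])^2 +
    ((g$x - 0.5) * vs[3] - center_um[3])^2
  array(d2 <= radius_um^2, dim = shape)
}

# match detected records to truth rows by nearest centroid; returns index
# into truth for each record
match_truth <- function(records, truth_table) {
  vapply(seq_len(nrow(records)), function(i) {
    which.min((truth_table$z_um - records$z_um[i])^2 +
                (truth_table$y_um - records$y_um[i])^2 +
                (truth_table$x_um - records$x_um[i])^2)
  }, integer(1))
}

# hand-rolled records table for classification/quantification tests
fake_records <- function(volumes, gfp_means = NULL, z_um = NULL,
                         marker_means = NULL) {
  n <- length(volumes)
  df <- data.frame(image_id = "fake", id = seq_len(n),
                   z_um = if (is.null(z_um)) rep(1, n) else z_um,
                   y_um = rep(1, n), x_um = rep(1, n),
                   volume_um3 = volumes)
  if (!is.null(gfp_means)) df$mean_gfp <- gfp_means
  if (!is.null(marker_means)) df$mean_marker <- marker_means
  df$size_class <- NA_character_
  df$clone <- NA
  df$depth_kept <- NA
  df
}
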