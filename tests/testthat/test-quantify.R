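# quantification module: counts, area ratios, marker ratios, spot counts

test_that("cell counting over depth-kept, classified records", {
  expect_equal(count_cells(empty_records(c("gfp"))),
               list(n_total = 0L, n_clone = 0L, n_small_clone = 0L))

  rec <- fake_records(c(30, 40, 50, 200, 250, 300, 35, 280))
  rec$size_class <- ifelse(rec$volume_um3 < 90, "small", "big")
  rec$clone <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  rec$depth_kept <- TRUE
  out <- count_cells(rec)
  expect_equal(out, list(n_total = 8L, n_clone = 3L, n_small_clone = 2L))

  rec$depth_kept <- FALSE
  expect_equal(count_cells(rec),
               list(n_total = 0L, n_clone = 0L, n_small_clone = 0L))

  bad <- fake_records(c(30, 40))
  expect_error(count_cells(bad), "classified")
})

test_that("positive-volume ratio: identities and phantom oracle", {
  ph <- generate_area_phantom(c(6L, 12L, 12L), c(1, 0.5, 0.5), 0.25,
                              seed = 4)
  expect_equal(positive_volume_ratio(ph$stack, "positive", "all",
                                     positive_threshold = 150),
               ph$realized_fraction)
  # positive mask == tissue mask -> 1; empty positive channel -> 0
  expect_equal(positive_volume_ratio(ph$stack, "tissue", "all",
                                     positive_threshold = 50), 1.0)
  expect_equal(positive_volume_ratio(ph$stack, "positive", "all",
                                     positive_threshold = 1e6), 0.0)

  # scale invariance under uniform voxel rescaling
  st2 <- image_stack(ph$stack$voxels, ph$stack$voxel_size_zyx * 3,
                     ph$stack$channel_names)
  expect_equal(positive_volume_ratio(st2, "positive", "all",
                                     positive_threshold = 150),
               ph$realized_fraction)

  # empty tissue mask -> NA with a warning, never 0
  expect_warning(
    r <- positive_volume_ratio(ph$stack, "positive", "tissue",
                               positive_threshold = 150,
                               tissue_threshold = 1e6),
    "undefined")
  expect_true(is.na(r))
})

test_that("marker-positive cell ratio", {
  rec <- fake_records(c(30, 40, 50, 60), marker_means = c(5, 80, 90, 7))
  rec$depth_kept <- TRUE
  expect_equal(marker_cell_ratio(rec, "marker", threshold = 0), 1.0)
  expect_equal(marker_cell_ratio(rec, "marker", threshold = 50), 0.5)
  expect_equal(marker_cell_ratio(rec, "marker", threshold = 1e6), 0.0)
  rec$depth_kept <- FALSE
  expect_true(is.na(marker_cell_ratio(rec, "marker", threshold = 50)))

  # generator oracle: marker rendered into a known subset, no noise
  p <- clean_params(n_small = 5L, n_big = 3L, seed = 23L)
  truth <- place_nuclei(p)
  ids <- truth$truth_table$id[1:3]
  stack <- render_channels(truth, p, marker_ids = ids)
  rec2 <- measure_nuclei(truth$label_map, stack)
  rec2$depth_kept <- TRUE
  expect_equal(marker_cell_ratio(rec2, "marker", threshold = 75), 3 / 8)
})

test_that("spot counting: blanks, known spot fields, volume window", {
  blank <- image_stack(array(0, dim = c(1, 6, 10, 10)), c(1, 1, 1), "ph3")
  expect_equal(count_spots(blank, "ph3", threshold = 10), 0L)

  # k disjoint bright balls -> k spots
  shape <- c(16L, 40L, 40L); vs <- c(1, 0.5, 0.5)
  m <- ball_mask(shape, vs, c(4, 4, 4), 1.5) |
    ball_mask(shape, vs, c(4, 14, 14), 1.5) |
    ball_mask(shape, vs, c(12, 6, 16), 1.5)
  ch <- array(0, dim = c(1, shape)); ch[1, , , ][m] <- 500
  st <- image_stack(ch, vs, "ph3")
  expect_equal(count_spots(st, "ph3", threshold = 100), 3L)
  # volume window excludes all three balls
  expect_equal(count_spots(st, "ph3", threshold = 100,
                           min_volume_um3 = 100), 0L)
  expect_error(count_spots(st, "ph3", threshold = 100,
                           min_volume_um3 = 5, max_volume_um3 = 1),
               "min_volume_um3")

  # additivity across a cut plane no spot crosses
  left <- st$voxels[, , , 1:20, drop = FALSE]
  right <- st$voxels[, , , 21:40, drop = FALSE]
  stl <- image_stack(left, vs, "ph3"); str <- image_stack(right, vs, "ph3")
  expect_equal(count_spots(stl, "ph3", threshold = 100) +
                 count_spots(str, "ph3", threshold = 100),
               count_spots(st, "ph3", threshold = 100))
})

test_that("summaries keep ratios in [0,1] and agree with count_cells", {
  p <- clean_params(n_small = 5L, n_big = 3L, seed = 29L)
  sim <- simulate_stack(p)
  res <- quantify_stack(sim$stack, run_config(images = data.frame()),
                        image_id = "img1")
  s <- res$summary
  for (col in c("clone_cell_ratio", "positive_volume_ratio")) {
    if (!is.na(s[[col]])) {
      expect_gte(s[[col]], 0); expect_lte(s[[col]], 1)
    }
  }
  cc <- count_cells(res$records)
  expect_equal(s$n_clone, cc$n_clone)
  expect_equal(s$n_total, cc$n_total)
})
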