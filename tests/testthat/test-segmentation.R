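# segmentation module: thresholding, watershed splitting, measurement

test_that("threshold edge cases follow the strict > rule", {
  vox <- array(0, dim = c(1, 4, 6, 6))
  st <- image_stack(vox, c(1, 1, 1), "dna")
  th <- threshold_nuclei(st, "dna", segmentation_params(threshold = 10))
  expect_false(any(th$mask))

  vox2 <- array(runif(4 * 6 * 6, 0, 50), dim = c(1, 4, 6, 6))
  st2 <- image_stack(vox2, c(1, 1, 1), "dna")
  th2 <- threshold_nuclei(st2, "dna",
                          segmentation_params(threshold = max(vox2)))
  expect_false(any(th2$mask))
})

test_that("auto threshold matches brute-force Otsu on a two-valued image", {
  vox <- array(10, dim = c(1, 4, 8, 8))
  hot <- sample(length(vox), 60)
  vox[hot] <- 200
  st <- image_stack(vox, c(1, 1, 1), "dna")
  th <- threshold_nuclei(st, "dna", segmentation_params(threshold = "auto"))
  got <- which(th$mask)
  expect_setequal(got, sort(hot))

  # brute-force oracle: exhaustive inter-class variance over all cut points
  v <- as.numeric(vox)
  cuts <- sort(unique(v))
  icv <- vapply(cuts[-length(cuts)], function(cut) {
    lo <- v[v <= cut]; hi <- v[v > cut]
    length(lo) / length(v) * (1 - length(lo) / length(v)) *
      (mean(lo) - mean(hi))^2
  }, numeric(1))
  best_cut <- cuts[which.max(icv)]   # foreground is v > best_cut
  expect_identical(v > th$threshold, v > best_cut)

  expect_error(otsu_threshold(rep(5, 100)), "constant")
})

test_that("two separated balls give two coextensive labels", {
  shape <- c(16L, 40L, 40L)
  vs <- c(1, 0.5, 0.5)
  m1 <- ball_mask(shape, vs, c(8, 5, 5), 3)
  m2 <- ball_mask(shape, vs, c(8, 15, 15), 3)
  lmap <- split_touching(m1 | m2, vs, segmentation_params())
  expect_equal(n_labels(lmap), 2L)
  lab <- lmap$labels
  id1 <- lab[9, 11, 11]   # voxel inside ball 1
  expect_true(id1 > 0L)
  expect_identical(lab == id1, m1)
  expect_identical(lab > 0L & lab != id1, m2)
})

test_that("a generator fused pair splits into 2 labels at >= 90% agreement", {
  p <- simulation_params(shape_zyx = c(24L, 96L, 96L), n_small = 0L,
                         n_big = 0L, n_touching_pairs = 1L, seed = 6L)
  sim <- simulate_stack(p)
  seg <- segment_stack(sim$stack)
  expect_equal(n_labels(seg$labels), 2L)
  tl <- sim$truth$label_map$labels
  sl <- seg$labels$labels
  pairvox <- tl > 0L
  tab <- table(tl[pairvox & sl > 0L], sl[pairvox & sl > 0L])
  expect_gte(sum(apply(tab, 1, max)) / sum(pairvox), 0.9)

  # with watershed disabled the pair stays one label
  segoff <- segment_stack(
    sim$stack, params = segmentation_params(watershed_enabled = FALSE))
  expect_equal(n_labels(segoff$labels), 1L)
})

test_that("empty mask yields an empty label map", {
  lmap <- split_touching(array(FALSE, dim = c(4, 6, 6)), c(1, 1, 1),
                         segmentation_params())
  expect_equal(n_labels(lmap), 0L)
})

test_that("partition property: label volumes sum to the mask volume", {
  p <- small_params(seed = 12L)
  sim <- simulate_stack(p)
  th <- threshold_nuclei(sim$stack)
  # disable the debris filter so the partition is against the raw mask
  lmap <- split_touching(th$mask, sim$stack$voxel_size_zyx,
                         segmentation_params(min_volume_um3 = 0))
  expect_equal(sum(lmap$labels > 0L), sum(th$mask))
  rec <- measure_nuclei(lmap, sim$stack)
  expect_equal(sum(rec$volume_um3),
               sum(th$mask) * voxel_volume(sim$stack))
})

test_that("watershed never decreases the label count", {
  for (s in c(4L, 9L)) {
    sim <- simulate_stack(small_params(seed = s,
                                       n_small = 5L, n_big = 2L))
    th <- threshold_nuclei(sim$stack)
    on_ <- split_touching(th$mask, sim$stack$voxel_size_zyx,
                          segmentation_params())
    off <- split_touching(th$mask, sim$stack$voxel_size_zyx,
                          segmentation_params(watershed_enabled = FALSE))
    expect_gte(n_labels(on_), n_labels(off))
  }
})

test_that("measurement: unit voxel, analytic ball, exact masked means", {
  # single-voxel label at voxel size (1.0, 0.5, 0.5) -> 0.25 um^3
  lab <- array(0L, dim = c(4, 4, 4)); lab[2, 2, 2] <- 1L
  vs <- c(1, 0.5, 0.5)
  st <- image_stack(array(7, dim = c(1, 4, 4, 4)), vs, "dna")
  rec <- measure_nuclei(label_map(lab, vs), st)
  expect_equal(rec$volume_um3, 0.25)
  expect_equal(rec$mean_dna, 7)
  expect_equal(rec[, c("z_um", "y_um", "x_um")],
               data.frame(z_um = 1.5, y_um = 0.75, x_um = 0.75))

  # digital ball of radius 5 um at isotropic 0.25 um voxels vs 4/3 pi r^3
  shape <- c(48L, 48L, 48L); vsi <- rep(0.25, 3)
  m <- ball_mask(shape, vsi, rep(6, 3), 5)
  sti <- image_stack(array(1, dim = c(1, shape)), vsi, "dna")
  reci <- measure_nuclei(label_map(array(as.integer(m), dim = shape), vsi),
                         sti)
  expect_equal(reci$volume_um3, 4 / 3 * pi * 125, tolerance = 0.02)

  # masked-mean oracle on a clean rendered clone nucleus
  p <- clean_params(seed = 33L, clone_fraction = 1)
  sim <- simulate_stack(p)
  recs <- measure_nuclei(sim$truth$label_map, sim$stack)
  expect_true(all(recs$mean_gfp == 200))
  expect_true(all(recs$mean_dna == 100))

  # idempotence
  recs2 <- measure_nuclei(sim$truth$label_map, sim$stack)
  expect_identical(recs, recs2)

  # geometry mismatch is an error
  bad <- image_stack(array(1, dim = c(1, 5, 5, 5)), vs, "dna")
  expect_error(measure_nuclei(label_map(lab, vs), bad), "shape")
})

test_that("volume recovery on clean generator stacks is within 10%", {
  sim <- simulate_stack(small_params(seed = 14L))
  seg <- segment_stack(sim$stack)
  tt <- sim$truth$truth_table
  expect_equal(nrow(seg$records), nrow(tt))
  m <- match_truth(seg$records, tt)
  expect_true(all(abs(seg$records$volume_um3 - tt$volume_um3[m]) /
                    tt$volume_um3[m] < 0.10))
})

test_that("border exclusion drops labels touching the image border", {
  shape <- c(10L, 20L, 20L); vs <- c(1, 0.5, 0.5)
  inside <- ball_mask(shape, vs, c(5, 5, 5), 2)
  touching <- array(FALSE, dim = shape)
  touching[1:3, 15:19, 15:19] <- TRUE     # touches z = 1 border
  mask <- inside | touching
  keep_all <- split_touching(mask, vs, segmentation_params())
  drop_border <- split_touching(mask, vs,
                                segmentation_params(exclude_border = TRUE))
  expect_equal(n_labels(keep_all), 2L)
  expect_equal(n_labels(drop_border), 1L)
})
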