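# Ground-truthed synthetic 3D stack generator.
#
# Emulates the midgut/disc imaging regime: two nuclear-volume populations
# (small progenitor-like vs big enterocyte-like) straddling ~90 um^3, a
# clone-positive subpopulation with elevated green intensity, optional fused
# nucleus pairs, anisotropic voxels (1 um z sections vs sub-um xy), PSF-like
# Gaussian blur and additive/Poisson noise. Ground truth (label map + truth
# table) is exact by construction, so every downstream stage has an oracle.

#' Simulation parameters for the synthetic stack generator
#'
#' Defaults state the reference imaging regime: a 128 x 128 x 30 voxel field
#' at (1.0, 0.31, 0.31) um voxels (1 um optical sections at typical 40x
#' confocal xy sampling), 15 small nuclei of 20-60 um^3 and 8 big nuclei of
#' 120-400 um^3 (populations straddling the ~90 um^3 size threshold), half of
#' the nuclei clone-positive with green intensity 200 vs 10, nuclear channel
#' at 100, PSF-like blur of (0.5, 0.3, 0.3) um, and additive Gaussian noise
#' of sd 10 (signal-to-noise 10 on the nuclear channel).
#'
#' @param shape_zyx voxel counts `(nz, ny, nx)`.
#' @param voxel_size_zyx micrometres per voxel `(z, y, x)`.
#' @param n_small,n_big counts of small- and big-population nuclei.
#' @param small_volume_range,big_volume_range target volume intervals (um^3);
#'   `max(small) < min(big)` is required.
#' @param clone_fraction probability that a nucleus is clone-positive.
#' @param clone_intensity,nonclone_intensity mean green-channel value inside
#'   clone-positive / clone-negative nuclei (arbitrary units).
#' @param nuclear_intensity mean DNA-channel value inside nuclei.
#' @param n_touching_pairs count of deliberately fused nucleus pairs (drawn
#'   from the big population as volume-matched spheres; centre distance
#'   0.9 x the sum of the radii along the joining axis, guaranteeing a
#'   single fused component before watershed while keeping both members
#'   separable).
#' @param blur_sigma_zyx Gaussian PSF proxy, um per axis; 0 disables.
#' @param noise_model `"none"`, `"gaussian"` (additive, sd `noise_scale`) or
#'   `"poisson"` (blurred image used as the rate).
#' @param noise_scale scale of the Gaussian noise (ignored for Poisson).
#' @param seed RNG seed; all generator randomness derives from it.
#' @return validated `simulation_params` object.
#' @export
simulation_params <- function(shape_zyx = c(30L, 128L, 128L),
                              voxel_size_zyx = c(1.0, 0.31, 0.31),
                              n_small = 15L, n_big = 8L,
                              small_volume_range = c(20, 60),
                              big_volume_range = c(120, 400),
                              clone_fraction = 0.5,
                              clone_intensity = 200,
                              nonclone_intensity = 10,
                              nuclear_intensity = 100,
                              n_touching_pairs = 0L,
                              blur_sigma_zyx = c(0.5, 0.12, 0.12),
                              noise_model = c("gaussian", "none", "poisson"),
                              noise_scale = 10,
                              seed = 1L) {
  noise_model <- match.arg(noise_model)
  p <- list(shape_zyx = as.integer(shape_zyx),
            voxel_size_zyx = as.numeric(voxel_size_zyx),
            n_small = as.integer(n_small), n_big = as.integer(n_big),
            small_volume_range = as.numeric(small_volume_range),
            big_volume_range = as.numeric(big_volume_range),
            clone_fraction = as.numeric(clone_fraction),
            clone_intensity = as.numeric(clone_intensity),
            nonclone_intensity = as.numeric(nonclone_intensity),
            nuclear_intensity = as.numeric(nuclear_intensity),
            n_touching_pairs = as.integer(n_touching_pairs),
            blur_sigma_zyx = as.numeric(blur_sigma_zyx),
            noise_model = noise_model,
            noise_scale = as.numeric(noise_scale),
            seed = as.integer(seed))
  if (length(p$shape_zyx) != 3L || any(p$shape_zyx < 1L)) {
    stop("shape_zyx must be 3 positive voxel counts")
  }
  if (length(p$voxel_size_zyx) != 3L || any(p$voxel_size_zyx <= 0)) {
    stop("voxel sizes must be positive")
  }
  if (p$n_small < 0L || p$n_big < 0L || p$n_touching_pairs < 0L) {
    stop("counts must be non-negative")
  }
  for (rg in list(p$small_volume_range, p$big_volume_range)) {
    if (length(rg) != 2L || any(rg <= 0) || rg[1] > rg[2]) {
      stop("volume ranges must be positive intervals")
    }
  }
  if (p$small_volume_range[2] >= p$big_volume_range[1]) {
    stop("small_volume_range must lie strictly below big_volume_range")
  }
  if (p$clone_fraction < 0 || p$clone_fraction > 1) {
    stop("clone_fraction must be in [0, 1]")
  }
  if (any(p$blur_sigma_zyx < 0) || p$noise_scale < 0) {
    stop("blur sigma and noise scale must be non-negative")
  }
  class(p) <- "simulation_params"
  p
}

# voxel-centre physical coordinate of 1-based index i along an axis
.vox_center <- function(i, step) (i - 0.5) * step

# voxel supports of an ellipsoid: returns (z,y,x) index matrix (1-based)
.ellipsoid_voxels <- function(center, semi, shape, vs) {
  lo <- pmax(1L, floor((center - semi) / vs))
  hi <- pmin(shape, ceiling((center + semi) / vs) + 1L)
  if (any(lo > hi)) return(matrix(integer(), ncol = 3L))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  g <- expand.grid(z = zi, y = yi, x = xi, KEEP.OUT.ATTRS = FALSE)
  dz <- (.vox_center(g$z, vs[1]) - center[1]) / semi[1]
  dy <- (.vox_center(g$y, vs[2]) - center[2]) / semi[2]
  dx <- (.vox_center(g$x, vs[3]) - center[3]) / semi[3]
  keep <- dz * dz + dy * dy + dx * dx <= 1
  as.matrix(g[keep, , drop = FALSE])
}

# semi-axes for a target volume with bounded anisotropy (<= ~2:1)
.sample_semi <- function(target_vol) {
  r0 <- (3 * target_vol / (4 * pi))^(1 / 3)
  sz <- stats::runif(1, 0.8, 1.25)
  sy <- stats::runif(1, 0.8, 1.25)
  sx <- 1 / (sz * sy)
  r0 * c(sz, sy, sx)
}

# grow/shrink semi-axes until the voxelised volume lands inside `rng`
.fit_volume <- function(center, semi, shape, vs, target, rng) {
  vv <- prod(vs)
  for (it in 1:25) {
    vox <- .ellipsoid_voxels(center, semi, shape, vs)
    vol <- nrow(vox) * vv
    if (vol >= rng[1] && vol <= rng[2]) return(list(vox = vox, vol = vol))
    if (vol <= 0) {
      semi <- semi * 1.3
    } else {
      semi <- semi * (target / vol)^(1 / 3)
    }
  }
  list(vox = vox, vol = vol, misfit = TRUE)
}

# linear indices of the chebyshev-r dilation of an index set, clipped to
# the domain
.dilate_lin <- function(vox, shape, r = 1L) {
  if (!nrow(vox)) return(integer(0))
  sh <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  out <- unlist(lapply(seq_len(nrow(sh)), function(s) {
    z <- vox[, 1] + sh[s, 1]; y <- vox[, 2] + sh[s, 2]
    x <- vox[, 3] + sh[s, 3]
    ok <- z >= 1 & z <= shape[1] & y >= 1 & y <= shape[2] &
      x >= 1 & x <= shape[3]
    z[ok] + shape[1] * (y[ok] - 1L) + shape[1] * shape[2] * (x[ok] - 1L)
  }), use.names = FALSE)
  unique(out)
}

.lin_idx <- function(vox, shape) {
  vox[, 1] + shape[1] * (vox[, 2] - 1L) + shape[1] * shape[2] * (vox[, 3] - 1L)
}

#' Place synthetic nuclei and return exact ground truth
#'
#' Nuclei are axis-aligned ellipsoids with anisotropy bounded near 2:1,
#' placed by rejection sampling so that non-pair nuclei are separated by at
#' least one voxel of background (26-connected gap). Touching pairs are two
#' overlapping ellipsoids whose fused support forms a single connected
#' component; overlap voxels belong to the nearer (ellipsoid-normalised)
#' centre. True volume is the assigned voxel count times the voxel volume.
#'
#' @param params a [simulation_params()].
#' @param max_attempts rejection-sampling cap per nucleus.
#' @return list of class `ground_truth`: `label_map` (a [label_map()]) and
#'   `truth_table` (data frame: id, z_um, y_um, x_um, volume_um3, size_class,
#'   clone, touching).
#' @export
place_nuclei <- function(params, max_attempts = 10000L) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  shape <- params$shape_zyx
  vs <- params$voxel_size_zyx
  vv <- prod(vs)
  labels <- array(0L, dim = shape)
  # occupancy pre-dilated by the 2-voxel clearance, so each placement
  # attempt only has to index its own voxels
  occ_dil <- array(FALSE, dim = shape)
  rows <- list()
  next_id <- 0L

  extent <- shape * vs
  sample_center <- function(semi) {
    # keep the ellipsoid inside the physical domain
    lo <- pmin(semi, extent / 2)
    c(stats::runif(1, lo[1], extent[1] - lo[1]),
      stats::runif(1, lo[2], extent[2] - lo[2]),
      stats::runif(1, lo[3], extent[3] - lo[3]))
  }

  # clearance of 2 voxels between distinct objects: the truth invariant
  # only needs >= 1 voxel of background, but the PSF halo of a neighbour
  # can bridge a single-voxel gap in the rendered mask
  admissible <- function(vox) {
    if (!nrow(vox)) return(FALSE)
    !any(occ_dil[.lin_idx(vox, shape)])
  }

  commit <- function(vox, size_class, touching) {
    next_id <<- next_id + 1L
    li <- .lin_idx(vox, shape)
    labels[li] <<- next_id
    occ_dil[.dilate_lin(vox, shape, r = 2L)] <<- TRUE
    ctr <- c(mean(.vox_center(vox[, 1], vs[1])),
             mean(.vox_center(vox[, 2], vs[2])),
             mean(.vox_center(vox[, 3], vs[3])))
    rows[[next_id]] <<- data.frame(
      id = next_id, z_um = ctr[1], y_um = ctr[2], x_um = ctr[3],
      volume_um3 = nrow(vox) * vv, size_class = size_class,
      clone = NA, touching = touching)
    next_id
  }

  fail <- function(kind) {
    stop(sprintf(paste0(
      "failed to place a %s nucleus after %d attempts; occupied fraction ",
      "%.2f of %.0f voxels -- reduce counts or enlarge the domain"),
      kind, max_attempts, mean(labels > 0L), prod(shape)))
  }

  place_population <- function(n, rng, size_class) {
    for (k in seq_len(n)) {
      target <- stats::runif(1, rng[1], rng[2])
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        semi <- .sample_semi(target)
        ctr <- sample_center(semi)
        fit <- .fit_volume(ctr, semi, shape, vs, target, rng)
        if (isTRUE(fit$misfit)) next
        if (admissible(fit$vox)) {
          commit(fit$vox, size_class, FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) fail(size_class)
    }
  }

  place_population(params$n_small, params$small_volume_range, "small")
  place_population(params$n_big, params$big_volume_range, "big")

  # fused pairs, drawn from the big population
  rngB <- params$big_volume_range
  for (k in seq_len(params$n_touching_pairs)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      tA <- stats::runif(1, rngB[1], rngB[2])
      tB <- stats::runif(1, rngB[1], rngB[2])
      # pair members are spheres: with elongated ellipsoids the 0.8 rule on
      # the joining axis can nearly engulf one member, which makes the pair
      # a single blob rather than two nuclei in contact with a neck
      semiA <- rep((3 * tA / (4 * pi))^(1 / 3), 3)
      semiB <- rep((3 * tB / (4 * pi))^(1 / 3), 3)
      axis <- sample(2:3, 1L)            # join laterally (y or x)
      ctrA <- sample_center(semiA + semiB)  # room for the partner
      # 0.9 x sum of radii: overlap deep enough to fuse (2-3 xy voxels)
      # while the smaller member keeps a distance-map prominence of at
      # least ~1.45 um, above the default watershed h_depth of 1 um
      d <- 0.9 * (semiA[axis] + semiB[axis])
      ctrB <- ctrA
      ctrB[axis] <- ctrA[axis] + d
      voxA <- .ellipsoid_voxels(ctrA, semiA, shape, vs)
      voxB <- .ellipsoid_voxels(ctrB, semiB, shape, vs)
      if (!nrow(voxA) || !nrow(voxB)) next
      liA <- .lin_idx(voxA, shape)
      liB <- .lin_idx(voxB, shape)
      shared <- intersect(liA, liB)
      if (!length(shared)) next          # must actually fuse
      # overlap voxels go to the nearer normalised centre
      ndist <- function(vox, ctr, semi) {
        rowSums(((cbind(.vox_center(vox[, 1], vs[1]),
                        .vox_center(vox[, 2], vs[2]),
                        .vox_center(vox[, 3], vs[3])) -
                    matrix(ctr, nrow(vox), 3, byrow = TRUE)) /
                   matrix(semi, nrow(vox), 3, byrow = TRUE))^2)
      }
      union_vox <- unique(rbind(voxA, voxB))
      # a voxel exclusive to one ellipsoid has normalised distance <= 1 for
      # it and > 1 for the other, so the global nearest-centre rule also
      # assigns exclusive voxels correctly
      toA <- ndist(union_vox, ctrA, semiA) <= ndist(union_vox, ctrB, semiB)
      keepA <- union_vox[toA, , drop = FALSE]
      keepB <- union_vox[!toA, , drop = FALSE]
      if (!nrow(keepA) || !nrow(keepB)) next
      if (!admissible(union_vox)) next
      commit(keepA, "big", TRUE)
      commit(keepB, "big", TRUE)
      placed <- TRUE
      break
    }
    if (!placed) fail("touching-pair")
  }

  tt <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), z_um = numeric(), y_um = numeric(),
               x_um = numeric(), volume_um3 = numeric(),
               size_class = character(), clone = logical(),
               touching = logical())
  tt$clone <- if (nrow(tt)) {
    stats::rbinom(nrow(tt), 1L, params$clone_fraction) == 1L
  } else logical(0)
  structure(list(label_map = label_map(labels, vs, compact = FALSE),
                 truth_table = tt),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d nuclei (%d clone-positive, %d touching)\n",
              nrow(x$truth_table), sum(x$truth_table$clone),
              sum(x$truth_table$touching)))
  invisible(x)
}

#' Render fluorescence channels from ground truth
#'
#' Forward model: piecewise-constant intensity on the label support (DNA
#' channel at `nuclear_intensity`; green channel at `clone_intensity` inside
#' clone-positive nuclei and `nonclone_intensity` inside the rest), Gaussian
#' blur as a PSF proxy, then noise. Noise is applied after blur; the Poisson
#' model uses the blurred image as its rate (standard fluorescence forward
#' model). Deterministic given `params$seed`.
#'
#' @param truth a `ground_truth` from [place_nuclei()].
#' @param params the [simulation_params()] used to build `truth`.
#' @param marker_ids optional integer vector of nucleus ids rendered into an
#'   extra `"marker"` channel at `marker_intensity`.
#' @param marker_intensity mean marker-channel value inside marked nuclei.
#' @return an [image_stack()] with channels `dna`, `gfp` and optionally
#'   `marker`.
#' @export
render_channels <- function(truth, params, marker_ids = NULL,
                            marker_intensity = 150) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(params, "simulation_params"))
  labels <- truth$label_map$labels
  if (!identical(dim(labels), as.integer(params$shape_zyx))) {
    stop("ground truth geometry does not match params$shape_zyx")
  }
  shape <- dim(labels)
  tt <- truth$truth_table
  inside <- labels > 0L

  dna <- array(0, dim = shape)
  dna[inside] <- params$nuclear_intensity

  gfp <- array(0, dim = shape)
  if (nrow(tt)) {
    lut <- numeric(max(tt$id))
    lut[tt$id] <- ifelse(tt$clone, params$clone_intensity,
                         params$nonclone_intensity)
    gfp[inside] <- lut[labels[inside]]
  }

  chans <- list(dna = dna, gfp = gfp)
  if (!is.null(marker_ids)) {
    marker <- array(0, dim = shape)
    if (length(marker_ids)) {
      marker[inside & array(labels %in% marker_ids, dim = shape)] <-
        marker_intensity
    }
    chans$marker <- marker
  }

  sig_vox <- params$blur_sigma_zyx / params$voxel_size_zyx
  if (any(sig_vox > 0)) {
    chans <- lapply(chans, function(ch) {
      array(.cpp_blur3d(as.numeric(ch), as.integer(shape), sig_vox),
            dim = shape)
    })
  }

  set.seed(params$seed + 500009L)
  chans <- lapply(chans, function(ch) {
    out <- switch(params$noise_model,
      none = ch,
      gaussian = ch + stats::rnorm(length(ch), 0, params$noise_scale),
      poisson = array(stats::rpois(length(ch), pmax(ch, 0)), dim = shape),
      stop(sprintf("unknown noise model '%s'", params$noise_model)))
    pmax(out, 0)
  })

  vox <- array(0, dim = c(length(chans), shape))
  for (i in seq_along(chans)) vox[i, , , ] <- chans[[i]]
  image_stack(vox, params$voxel_size_zyx, names(chans), "low_z")
}

#' Generate a stack and its ground truth in one call
#'
#' @inheritParams render_channels
#' @param params a [simulation_params()].
#' @return list with `truth` (ground truth) and `stack` ([image_stack()]).
#' @export
simulate_stack <- function(params, marker_ids = NULL,
                           marker_intensity = 150) {
  truth <- place_nuclei(params)
  stack <- render_channels(truth, params, marker_ids = marker_ids,
                           marker_intensity = marker_intensity)
  list(truth = truth, stack = stack)
}

#' Area phantom with exactly known positive-voxel fraction
#'
#' Builds a stack whose `tissue` channel covers the whole domain and whose
#' `positive` channel covers a contiguous run of voxels of known count,
#' placed at a seeded random offset. The realised fraction (positive voxels /
#' total voxels) is returned exactly; it may differ from the request by
#' discretisation only.
#'
#' @param shape_zyx voxel counts `(nz, ny, nx)`.
#' @param voxel_size_zyx micrometres per voxel.
#' @param positive_fraction requested fraction in `[0, 1]`.
#' @param seed RNG seed for the placement offset.
#' @return list: `stack` (an [image_stack()] with channels `tissue`,
#'   `positive`) and `realized_fraction`.
#' @export
generate_area_phantom <- function(shape_zyx, voxel_size_zyx = c(1, 1, 1),
                                  positive_fraction, seed = 1L) {
  if (positive_fraction < 0 || positive_fraction > 1) {
    stop("positive_fraction must be in [0, 1]")
  }
  shape <- as.integer(shape_zyx)
  n <- prod(shape)
  n_pos <- round(positive_fraction * n)
  set.seed(as.integer(seed))
  start <- if (n_pos %in% c(0L, n)) 1L else sample.int(n - n_pos + 1L, 1L)
  tissue <- array(100, dim = shape)
  positive <- array(0, dim = shape)
  if (n_pos > 0) positive[start:(start + n_pos - 1L)] <- 200
  vox <- array(0, dim = c(2L, shape))
  vox[1, , , ] <- tissue
  vox[2, , , ] <- positive
  list(stack = image_stack(vox, voxel_size_zyx, c("tissue", "positive")),
       realized_fraction = n_pos / n)
}
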