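#' Configuration of the synthetic lumbosacral spine phantom
#'
#' The phantom emulates a lumbosacral specimen with six vertebrae (L1-L6)
#' rigidly fixed to a frame carrying four infrared-reflective fiducial
#' spheres. Vertebrae are parametric primitives (spinous fin, lamina slabs,
#' articular knobs, transverse bars, body cylinder) voxelised at the base
#' spacing; successive spinous processes are separated by the configured
#' inter-level distances, given from the most caudal pair (L6/L5) to the
#' most cranial pair (L2/L1). Levels are indexed 1..n for L1..Ln, with L1
#' the most cranial (largest z in LPS).
#'
#' @param n_levels number of vertebral levels (default 6).
#' @param inter_level_distances_mm successive spinous-process distances,
#'   caudal pair first (defaults are the measured study values).
#' @param base_spacing_mm isotropic voxel size of the base volume (mm).
#' @param vertebra_shape per-region primitive dimensions in mm; see
#'   [default_vertebra_shape()].
#' @param fiducial_centers_mm 4 x 3 matrix of sphere centres (mm, CT space).
#' @param fiducial_radius_mm sphere radius (mm).
#' @param hu_bone,hu_soft,hu_sphere CT intensity levels (HU-like).
#' @param hu_noise_sd standard deviation of additive CT noise.
#' @param seed integer RNG seed controlling the CT noise.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_levels = 6,
                           inter_level_distances_mm = c(69.36, 35.33, 38.21, 39.38, 39.46),
                           base_spacing_mm = 0.5,
                           vertebra_shape = default_vertebra_shape(),
                           fiducial_centers_mm = default_fiducial_centers(),
                           fiducial_radius_mm = 5.5,
                           hu_bone = 700, hu_soft = 40, hu_sphere = 3200,
                           hu_noise_sd = 6,
                           seed = 1L) {
  stopifnot(n_levels >= 1, base_spacing_mm > 0)
  if (length(inter_level_distances_mm) != n_levels - 1) {
    stop("phantom_config: need n_levels - 1 inter-level distances")
  }
  if (n_levels > 1 && any(inter_level_distances_mm <= 0)) {
    stop("phantom_config: inter-level distances must be positive")
  }
  fiducial_centers_mm <- point_set(fiducial_centers_mm)
  if (nrow(fiducial_centers_mm) != 4) {
    stop("phantom_config: the study frame carries exactly 4 fiducial spheres")
  }
  structure(list(n_levels = as.integer(n_levels),
                 inter_level_distances_mm = as.numeric(inter_level_distances_mm),
                 base_spacing_mm = base_spacing_mm,
                 vertebra_shape = vertebra_shape,
                 fiducial_centers_mm = fiducial_centers_mm,
                 fiducial_radius_mm = fiducial_radius_mm,
                 hu_bone = hu_bone, hu_soft = hu_soft, hu_sphere = hu_sphere,
                 hu_noise_sd = hu_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Default vertebra primitive dimensions (mm)
#'
#' All values are relative to the level centre: x lateral, y posterior
#' (the spinous apex is the most posterior point), z superior. The
#' posterior surfaces are curved (parabolic spinous crest, laterally
#' sloped lamina roofs, ellipsoidal articular knobs, rounded transverse
#' bars, cylindrical body) so the voxelised surface has no flat
#' lattice-aligned plateaus — important both for anatomical plausibility
#' and so surface registration is well conditioned.
#'
#' @export
default_vertebra_shape <- function() {
  list(
    sp  = list(half_x = 2.5, y_min = 8, y_max = 26, half_z = 5, crest_drop = 0.2),
    lam = list(x_min = 2.5, x_max = 9, y_min = 2, y_max = 8,  half_z = 7,
               slope_x = 0.5, curve_z = 0.08),
    ap  = list(x_center = 10, y_center = 8.5, z_center = 8,
               rx = 4, ry = 4.5, rz = 3.5),
    tp  = list(x_min = 8.5, x_max = 30, y_center = -3, ry = 3, rz = 3,
               droop_x = 0.12),
    vb  = list(center_y = -15, radius = 13, half_z = 14, barrel = 0.008)
  )
}

#' @rdname default_vertebra_shape
#' @export
default_fiducial_centers <- function() {
  rbind(c(-36, -32, 70), c(-36, -30, 205), c(36, -30, 55), c(36, -28, 190))
}

# region codes within a level; labelmap code = level * 10 + region
REGIONS <- c(SP = 1L, L = 2L, AP = 3L, TP = 4L, VB = 5L)
COVERAGE_BINS <- c("SP", "L", "AP", "TP", "VB", "Inf", "Sup")

#' @rdname generate_phantom
#' @export
label_level <- function(code) code %/% 10L

#' @rdname generate_phantom
#' @export
label_region <- function(code) code %% 10L

# run code with a private RNG stream, restoring the caller's seed
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# index range of a world interval on one axis (clamped)
axis_range <- function(lo, hi, origin, spacing, n) {
  i0 <- max(1L, ceiling((lo - origin) / spacing + 1 - 1e-9))
  i1 <- min(n, floor((hi - origin) / spacing + 1 + 1e-9))
  if (i0 > i1) return(NULL)
  i0:i1
}

#' Generate the synthetic spine phantom
#'
#' Builds the base-resolution labelmap and CT-like volume, per-level surface
#' landmarks (7 per vertebra: spinous apex, left/right laminae, left/right
#' superior articular processes, left/right transverse tips, each snapped to
#' the nearest labelled voxel centre of its level) and the fiducial spheres
#' rendered as bright blobs in the CT volume. Deterministic for a given
#' config seed.
#'
#' @param config a [phantom_config()].
#' @return A `spine_phantom` list: `labelmap` and `ct` ([volume3d()]),
#'   `landmarks` (per level, 7 x 3 named matrices, CT mm), `fiducials`
#'   (4 x 3, sorted lexicographically), `level_centers_z`,
#'   `level_centroids`, `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  sh <- config$vertebra_shape
  sp <- config$base_spacing_mm
  nl <- config$n_levels
  # level centres along z, caudal (Ln) to cranial (L1)
  z_caudal <- 25
  z_up <- z_caudal + c(0, cumsum(config$inter_level_distances_mm))
  level_z <- rev(z_up)                                   # index 1 = L1 (cranial)
  half_z_max <- max(sh$sp$half_z, sh$lam$half_z, sh$ap$z_center + sh$ap$rz,
                    sh$tp$rz, sh$vb$half_z)
  if (nl > 1 && any(config$inter_level_distances_mm < 2 * half_z_max + sp)) {
    stop("generate_phantom: vertebra primitives overlap across levels; ",
         "reduce primitive z extents or increase inter-level distances")
  }
  fid <- config$fiducial_centers_mm
  r_f <- config$fiducial_radius_mm
  x_max <- max(sh$tp$x_max, abs(fid[, 1]) + r_f) + 6
  y_lim <- c(min(sh$vb$center_y - sh$vb$radius, fid[, 2] - r_f) - 4,
             max(sh$sp$y_max, fid[, 2] + r_f) + 6)
  z_lim <- c(min(0, fid[, 3] - r_f - 4),
             max(level_z[1] + half_z_max + 25, fid[, 3] + r_f + 4))
  origin <- c(-x_max, y_lim[1], z_lim[1])
  dims <- as.integer(floor(c(2 * x_max, diff(y_lim), diff(z_lim)) / sp)) + 1L
  xs <- origin[1] + (seq_len(dims[1]) - 1) * sp
  ys <- origin[2] + (seq_len(dims[2]) - 1) * sp
  zs <- origin[3] + (seq_len(dims[3]) - 1) * sp
  lab <- array(0L, dim = dims)

  # evaluate a world-coordinate predicate on the bounding-box subgrid and
  # assign the code where it holds (later fills overwrite earlier ones)
  fill_region <- function(x0, x1, y0, y1, z0, z1, code, pred) {
    ix <- axis_range(x0, x1, origin[1], sp, dims[1])
    iy <- axis_range(y0, y1, origin[2], sp, dims[2])
    iz <- axis_range(z0, z1, origin[3], sp, dims[3])
    if (is.null(ix) || is.null(iy) || is.null(iz)) return(invisible())
    nx <- length(ix); ny <- length(iy); nz <- length(iz)
    X <- array(xs[ix], c(nx, ny, nz))
    Y <- array(rep(ys[iy], each = nx), c(nx, ny, nz))
    Z <- array(rep(zs[iz], each = nx * ny), c(nx, ny, nz))
    m <- pred(X, Y, Z)
    if (any(m)) {
      subv <- lab[ix, iy, iz, drop = FALSE]
      subv[m] <- code
      lab[ix, iy, iz] <<- subv
    }
    invisible()
  }

  for (lv in seq_len(nl)) {
    cz <- level_z[lv]
    code <- function(region) lv * 10L + REGIONS[[region]]
    # fill posterior-most regions last so overlaps resolve to the shallower label
    vb <- sh$vb
    fill_region(-vb$radius, vb$radius, vb$center_y - vb$radius,
                vb$center_y + vb$radius, cz - vb$half_z, cz + vb$half_z,
                code("VB"), function(X, Y, Z) {
                  # barrel shape: radius shrinks towards the end plates
                  X^2 + (Y - vb$center_y)^2 <=
                    (vb$radius - vb$barrel * (Z - cz)^2)^2
                })
    tp <- sh$tp
    for (s in c(-1, 1)) {
      fill_region(min(s * tp$x_min, s * tp$x_max), max(s * tp$x_min, s * tp$x_max),
                  tp$y_center - tp$droop_x * (tp$x_max - tp$x_min) - tp$ry,
                  tp$y_center + tp$ry,
                  cz - tp$rz, cz + tp$rz,
                  code("TP"), function(X, Y, Z) {
                    # the bar droops anteriorly towards its lateral tip
                    yc <- tp$y_center - tp$droop_x * (abs(X) - tp$x_min)
                    ((Y - yc) / tp$ry)^2 + ((Z - cz) / tp$rz)^2 <= 1
                  })
    }
    lm_ <- sh$lam
    for (s in c(-1, 1)) {
      fill_region(min(s * lm_$x_min, s * lm_$x_max), max(s * lm_$x_min, s * lm_$x_max),
                  lm_$y_min, lm_$y_max, cz - lm_$half_z, cz + lm_$half_z,
                  code("L"), function(X, Y, Z) {
                    Y <= lm_$y_max - lm_$slope_x * (abs(X) - lm_$x_min) -
                      lm_$curve_z * (Z - cz)^2
                  })
    }
    ap <- sh$ap
    for (s in c(-1, 1)) for (zo in c(-1, 1)) {
      zc <- cz + zo * ap$z_center
      fill_region(s * ap$x_center - ap$rx, s * ap$x_center + ap$rx,
                  ap$y_center - ap$ry, ap$y_center + ap$ry,
                  zc - ap$rz, zc + ap$rz,
                  code("AP"), function(X, Y, Z) {
                    ((X - s * ap$x_center) / ap$rx)^2 +
                      ((Y - ap$y_center) / ap$ry)^2 +
                      ((Z - zc) / ap$rz)^2 <= 1
                  })
    }
    spn <- sh$sp
    fill_region(-spn$half_x, spn$half_x, spn$y_min, spn$y_max,
                cz - spn$half_z, cz + spn$half_z,
                code("SP"), function(X, Y, Z) {
                  Y <= spn$y_max - spn$crest_drop * (Z - cz)^2
                })
  }

  ct <- array(config$hu_soft, dim = dims)
  ct[lab > 0L] <- config$hu_bone
  # fiducial spheres: bright, outside the anatomy, not part of the labelmap
  for (f in seq_len(nrow(fid))) {
    c_f <- fid[f, ]
    ix <- axis_range(c_f[1] - r_f, c_f[1] + r_f, origin[1], sp, dims[1])
    iy <- axis_range(c_f[2] - r_f, c_f[2] + r_f, origin[2], sp, dims[2])
    iz <- axis_range(c_f[3] - r_f, c_f[3] + r_f, origin[3], sp, dims[3])
    if (is.null(ix) || is.null(iy) || is.null(iz)) {
      stop("generate_phantom: fiducial sphere outside the volume extent")
    }
    d2 <- outer(outer((xs[ix] - c_f[1])^2, (ys[iy] - c_f[2])^2, "+"), (zs[iz] - c_f[3])^2, "+")
    sub <- ct[ix, iy, iz, drop = FALSE]
    sub[d2 <= r_f^2] <- config$hu_sphere
    ct[ix, iy, iz] <- sub
  }
  ct <- ct + with_seed(config$seed, array(stats::rnorm(prod(dims), 0, config$hu_noise_sd), dims))

  labelmap <- volume3d(lab, spacing = sp, origin = origin)
  ctvol <- volume3d(ct, spacing = sp, origin = origin)

  landmark_names <- c("spinous_apex", "lamina_left", "lamina_right",
                      "sup_articular_left", "sup_articular_right",
                      "transverse_tip_left", "transverse_tip_right")
  snap <- function(p, lv) {
    idx <- round(world_to_index(labelmap, p))
    rad <- 6L
    ix <- max(1L, idx[1] - rad):min(dims[1], idx[1] + rad)
    iy <- max(1L, idx[2] - rad):min(dims[2], idx[2] + rad)
    iz <- max(1L, idx[3] - rad):min(dims[3], idx[3] + rad)
    sub <- lab[ix, iy, iz, drop = FALSE]
    w <- which(label_level(sub) == lv, arr.ind = TRUE)
    if (nrow(w) == 0) stop("generate_phantom: no labelled voxel near a landmark")
    cand <- cbind(ix[w[, 1]], iy[w[, 2]], iz[w[, 3]])
    wc <- index_to_world(labelmap, cand)
    d2 <- rowSums(sweep(wc, 2, as.numeric(p))^2)
    wc[which.min(d2), ]
  }
  landmarks <- vector("list", nl)
  half_vox <- sp / 2
  for (lv in seq_len(nl)) {
    cz <- level_z[lv]
    lam_mid_x <- (sh$lam$x_min + sh$lam$x_max) / 2
    lam_top <- sh$lam$y_max - sh$lam$slope_x * (lam_mid_x - sh$lam$x_min)
    raw <- rbind(
      c(0, sh$sp$y_max - half_vox, cz),
      c(-lam_mid_x, lam_top - half_vox, cz),
      c(lam_mid_x, lam_top - half_vox, cz),
      c(-sh$ap$x_center, sh$ap$y_center + sh$ap$ry - half_vox, cz + sh$ap$z_center),
      c(sh$ap$x_center, sh$ap$y_center + sh$ap$ry - half_vox, cz + sh$ap$z_center),
      c(-(sh$tp$x_max - half_vox), sh$tp$y_center, cz),
      c(sh$tp$x_max - half_vox, sh$tp$y_center, cz))
    lm_mat <- t(apply(raw, 1, snap, lv = lv))
    rownames(lm_mat) <- landmark_names
    landmarks[[lv]] <- lm_mat
  }

  # per-level labelled-voxel centroids (used to initialise registration)
  level_centroids <- matrix(NA_real_, nl, 3)
  idx_lab <- which(lab > 0L)
  lv_of <- label_level(lab[idx_lab])
  ai <- arrayInd(idx_lab, dims)
  wpts <- index_to_world(labelmap, ai)
  for (lv in seq_len(nl)) level_centroids[lv, ] <- colMeans(wpts[lv_of == lv, , drop = FALSE])

  fid_sorted <- fid[canonical_fiducial_order(fid), , drop = FALSE]
  structure(list(labelmap = labelmap, ct = ctvol,
                 landmarks = landmarks, landmark_names = landmark_names,
                 fiducials = point_set(fid_sorted, frame = "CT"),
                 level_centers_z = level_z,
                 level_centroids = level_centroids,
                 config = config),
            class = "spine_phantom")
}

#' @export
print.spine_phantom <- function(x, ...) {
  cat(sprintf("<spine_phantom> %d levels, %s voxels at %.3g mm, %d fiducials\n",
              x$config$n_levels, paste(vol_dim(x$labelmap), collapse = "x"),
              x$config$base_spacing_mm, nrow(x$fiducials)))
  invisible(x)
}

#' Resample the phantom CT to a coarser isotropic resolution
#'
#' Linear interpolation onto an isotropic grid covering the same physical
#' extent, emulating CT reconstructions at different voxel sizes.
#'
#' @param phantom a `spine_phantom`.
#' @param spacing_mm target spacing; must be at least the base spacing.
#' @export
resample_ct <- function(phantom, spacing_mm) {
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 || spacing_mm <= 0) {
    stop("resample_ct: spacing must be a positive scalar")
  }
  if (spacing_mm < phantom$config$base_spacing_mm - 1e-12) {
    stop("resample_ct: spacing must be >= the base spacing")
  }
  vol_resample(phantom$ct, spacing_mm, method = "linear")
}

#' @rdname resample_ct
#' @export
resample_labelmap <- function(phantom, spacing_mm) {
  if (spacing_mm < phantom$config$base_spacing_mm - 1e-12) {
    stop("resample_labelmap: spacing must be >= the base spacing")
  }
  vol_resample(phantom$labelmap, spacing_mm, method = "nearest")
}

#' Write phantom landmarks and fiducials as CSV
#'
#' Columns `level,name,x,y,z` in mm (LPS, CT space); fiducials use level 0.
#'
#' @param phantom a `spine_phantom`.
#' @param path output CSV path.
#' @export
write_landmarks_csv <- function(phantom, path) {
  rows <- do.call(rbind, lapply(seq_along(phantom$landmarks), function(lv) {
    m <- phantom$landmarks[[lv]]
    data.frame(level = lv, name = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  fid <- data.frame(level = 0, name = paste0("fiducial_", seq_len(nrow(phantom$fiducials))),
                    x = phantom$fiducials[, 1], y = phantom$fiducials[, 2],
                    z = phantom$fiducials[, 3])
  utils::write.csv(rbind(rows, fid), path, row.names = FALSE)
  invisible(path)
}
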