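# Shared fixtures. Expensive objects (phantoms, the full simulated study)
# are built once per session and memoised so every test file can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, make(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# random rigid transform with rotation up to max_angle_deg
random_rigid <- function(seed, max_angle_deg = 180, max_trans_mm = 50) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  perturb_transform(rt_identity(),
                    angle_deg = runif(1, -max_angle_deg, max_angle_deg),
                    axis = ax,
                    translation_mm = runif(3, -max_trans_mm, max_trans_mm))
}

# small two-level phantom at 1 mm spacing: fast, exercises all structures
tiny_phantom_config <- function(seed = 7L) {
  phantom_config(
    n_levels = 2, inter_level_distances_mm = 40,
    base_spacing_mm = 1,
    fiducial_centers_mm = rbind(c(-36, -32, 20), c(-36, -30, 75),
                                c(36, -30, 15), c(36, -28, 70)),
    seed = seed)
}

tiny_phantom <- function() fixture("tiny_phantom", function() {
  generate_phantom(tiny_phantom_config())
})

# the full default phantom (6 levels, 0.5 mm base spacing)
default_phantom <- function() fixture("default_phantom", function() {
  generate_phantom(phantom_config())
})

# full simulated study at the base CT resolution (120 acquisitions)
study_run <- function() fixture("study_run", function() {
  run_experiment(experiment_config(ct_resolutions_mm = 0.5, master_seed = 42L))
})

# single-level labelled slab: a thin plate of one region code, useful for
# constructed registration / coverage scenarios
slab_labelmap <- function(code = 12L, dims = c(40, 40, 40), spacing = 1,
                          j_slab = 20L, thickness = 1L) {
  lab <- array(0L, dims)
  lab[, j_slab:(j_slab + thickness - 1L), ] <- code
  volume3d(lab, spacing = spacing, origin = c(0, 0, 0))
}

# hand-built tracked sweep from poses only (images optional); used by tests
# that exercise pose-driven operations (coverage, cloud mapping)
make_test_sweep <- function(poses, n_cols = 8L, pixel_spacing_mm = 1.2,
                            depth_cm = 4, level = 2L, images = NULL) {
  frames <- lapply(seq_along(poses), function(i) {
    structure(list(image = if (is.null(images)) NULL else images[[i]],
                   pose = poses[[i]]), class = "tracked_frame")
  })
  structure(list(frames = frames,
                 config = list(n_cols = as.integer(n_cols),
                               pixel_spacing_mm = pixel_spacing_mm,
                               depth_cm = depth_cm),
                 level = as.integer(level)),
            class = "tracked_sweep")
}

# downward-looking probe pose (image x -> +x, depth -> -y) at a position
probe_pose_at <- function(x, y, z) {
  m <- diag(4)
  m[1:3, 1:3] <- cbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  m[1:3, 4] <- c(x, y, z)
  rigid_transform(m)
}

# independent brute-force coverage oracle: per-ray nested marching at a
# fine step, first labelled voxel wins, unique-voxel binning
coverage_oracle <- function(sweep, labelmap, t_gt, level, step = NULL) {
  if (is.null(step)) step <- min(labelmap$spacing) / 10
  counts <- stats::setNames(integer(7), c("SP", "L", "AP", "TP", "VB", "Inf", "Sup"))
  hits <- integer(0)
  d <- dim(labelmap$data)
  for (f in sweep$frames) {
    m <- unclass(compose(t_gt, f$pose))
    for (cc in seq_len(sweep$config$n_cols)) {
      u <- (cc - (sweep$config$n_cols + 1) / 2) * sweep$config$pixel_spacing_mm
      o <- as.numeric(m[1:3, 1:3] %*% c(u, 0, 0) + m[1:3, 4])
      dir <- m[1:3, 2]
      for (s in seq(0, sweep$config$depth_cm * 10, by = step)) {
        p <- o + s * dir
        ijk <- round((p - labelmap$origin) / labelmap$spacing) + 1
        if (any(ijk < 1) || any(ijk > d)) next
        lb <- labelmap$data[ijk[1], ijk[2], ijk[3]]
        if (lb > 0) {
          hits <- c(hits, (ijk[3] - 1) * d[1] * d[2] + (ijk[2] - 1) * d[1] + ijk[1])
          break
        }
      }
    }
  }
  if (length(hits)) {
    vox <- unique(hits)
    code <- labelmap$data[vox]
    lv <- code %/% 10L
    rg <- code %% 10L
    regions <- c(SP = 1L, L = 2L, AP = 3L, TP = 4L, VB = 5L)
    for (b in seq_along(regions)) {
      counts[names(regions)[b]] <- sum(lv == level & rg == regions[[b]])
    }
    counts["Inf"] <- sum(lv == level + 1L)
    counts["Sup"] <- sum(lv == level - 1L)
  }
  counts
}

# random small labelled scene + sweep for coverage oracle comparisons
random_coverage_scene <- function(seed) {
  set.seed(seed)
  d <- sample(16:32, 3, replace = TRUE)
  lab <- array(0L, d)
  for (b in seq_len(sample(2:4, 1))) {
    lv <- sample(1:3, 1); rg <- sample(1:5, 1)
    i0 <- sample(1:(d[1] - 4), 1); j0 <- sample(1:(d[2] - 4), 1)
    k0 <- sample(1:(d[3] - 4), 1)
    lab[i0:(i0 + sample(2:4, 1)), j0:(j0 + sample(2:4, 1)),
        k0:(k0 + sample(2:4, 1))] <- lv * 10L + rg
  }
  lm <- volume3d(lab, spacing = 1, origin = c(0, 0, 0))
  nf <- sample(1:3, 1)
  poses <- lapply(seq_len(nf), function(i) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    perturb_transform(probe_pose_at(runif(1, 4, d[1] - 4), d[2] + 2,
                                    runif(1, 4, d[3] - 4)),
                      angle_deg = runif(1, -15, 15), axis = ax,
                      pivot = d / 2)
  })
  list(labelmap = lm, sweep = make_test_sweep(poses))
}
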