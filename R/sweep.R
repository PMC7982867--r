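#' Configuration of a simulated tracked ultrasound sweep
#'
#' Frames are 2D images with rows along the beam (depth) axis and columns
#' along the lateral axis. The image grid has a fixed number of rows; the
#' pixel spacing is therefore `depth / image_rows` mm (deeper settings are
#' coarser), and the number of columns follows from the fixed 14 mm probe
#' contact width. The echo placed at the bone surface has a Gaussian axial
#' profile whose width shrinks with frequency (`sigma_mm = 7.2 / f_MHz`)
#' and an amplitude attenuated with depth and frequency.
#'
#' One seed drives the whole sweep; it is split into a pose stream
#' (`pose_seed`, default `seed`) controlling repetition jitter and per-frame
#' pose noise, and a speckle stream (`speckle_seed`, default
#' `seed + 500009`) controlling image texture, so pose and texture
#' randomness are independently reproducible.
#'
#' @param depth_cm imaging depth, 5 or 7 cm (the study grid).
#' @param frequency_mhz probe frequency, 6 or 12 MHz (the study grid).
#' @param n_frames frames per sweep.
#' @param frame_width_mm probe contact width (fixed 14 mm).
#' @param image_rows rows of the image grid (pixel spacing follows).
#' @param sweep_span_mm caudo-cranial travel of the sweep, centred on the
#'   scanned level.
#' @param jitter_angle_sd_deg SD of the per-repetition left-right rocking
#'   about the travel axis (degrees); the beam fans laterally at depth.
#' @param jitter_lateral_sd_mm SD of the per-repetition lateral offset (mm).
#' @param frame_noise_mm,frame_noise_deg SD of small per-frame pose noise.
#' @param speckle_ceiling maximum speckle amplitude (image units in [0,1]).
#' @param echo_amplitude peak echo amplitude before attenuation.
#' @param attenuation_per_mm_mhz depth-and-frequency attenuation rate.
#' @param seed integer seed; see Details for the split.
#' @param pose_seed,speckle_seed optional explicit sub-stream seeds.
#' @export
sweep_config <- function(depth_cm = 5, frequency_mhz = 6, n_frames = 24,
                         frame_width_mm = 14, image_rows = 128,
                         sweep_span_mm = 56,
                         jitter_angle_sd_deg = 2, jitter_lateral_sd_mm = 1,
                         frame_noise_mm = 0.1, frame_noise_deg = 0.05,
                         speckle_ceiling = 0.18, echo_amplitude = 0.95,
                         attenuation_per_mm_mhz = 8e-4,
                         seed = 1L, pose_seed = NULL, speckle_seed = NULL) {
  if (!depth_cm %in% c(5, 7)) stop("sweep_config: depth must be 5 or 7 cm")
  if (!frequency_mhz %in% c(6, 12)) stop("sweep_config: frequency must be 6 or 12 MHz")
  stopifnot(n_frames >= 1, image_rows >= 8, frame_width_mm > 0, sweep_span_mm > 0)
  if (jitter_angle_sd_deg < 0 || jitter_lateral_sd_mm < 0 ||
      frame_noise_mm < 0 || frame_noise_deg < 0) {
    stop("sweep_config: jitter magnitudes must be non-negative")
  }
  pixel_spacing_mm <- depth_cm * 10 / image_rows
  n_cols <- max(4L, as.integer(floor(frame_width_mm / pixel_spacing_mm)))
  structure(list(depth_cm = depth_cm, frequency_mhz = frequency_mhz,
                 n_frames = as.integer(n_frames),
                 frame_width_mm = frame_width_mm,
                 image_rows = as.integer(image_rows), n_cols = n_cols,
                 pixel_spacing_mm = pixel_spacing_mm,
                 sweep_span_mm = sweep_span_mm,
                 jitter_angle_sd_deg = jitter_angle_sd_deg,
                 jitter_lateral_sd_mm = jitter_lateral_sd_mm,
                 frame_noise_mm = frame_noise_mm, frame_noise_deg = frame_noise_deg,
                 speckle_ceiling = speckle_ceiling, echo_amplitude = echo_amplitude,
                 attenuation_per_mm_mhz = attenuation_per_mm_mhz,
                 echo_sigma_mm = 7.2 / frequency_mhz,
                 seed = as.integer(seed),
                 pose_seed = as.integer(if (is.null(pose_seed)) seed else pose_seed),
                 speckle_seed = as.integer(if (is.null(speckle_seed)) seed + 500009L else speckle_seed)),
            class = "sweep_config")
}

# base frame orientation in CT space: image x -> +x (lateral), image depth
# -> -y (posterior to anterior), image normal -> -z; det = +1
base_probe_rotation <- function() {
  cbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1))
}

#' Plan the frame poses of a caudo-cranial sweep
#'
#' Poses progress from the inferior to the superior aspect of the level,
#' with the image depth axis pointing antero-posteriorly into the anatomy.
#' Per-repetition jitter (left-right tilt about the beam axis and a lateral
#' offset) plus small per-frame pose noise are drawn from the config's pose
#' stream. Poses map image-plane millimetre coordinates to the reference
#' space (via `ref_to_ct` when the tracker frame differs from CT).
#'
#' @param phantom a `spine_phantom`.
#' @param level vertebral level index (1 = most cranial).
#' @param config a [sweep_config()].
#' @param ref_to_ct the true reference-to-CT transform of the scene
#'   (identity when simulating directly in CT space).
#' @return list of `rigid_transform` frame poses (image -> reference).
#' @export
plan_sweep_poses <- function(phantom, level, config, ref_to_ct = rt_identity()) {
  if (level < 1 || level > phantom$config$n_levels) {
    stop("plan_sweep_poses: level out of range")
  }
  cz <- phantom$level_centers_z[level]
  n <- config$n_frames
  zf <- if (n == 1) cz else seq(cz - config$sweep_span_mm / 2,
                                cz + config$sweep_span_mm / 2, length.out = n)
  y_probe <- phantom$config$vertebra_shape$sp$y_max + 2
  ct_to_ref <- invert(ref_to_ct)
  with_seed(config$pose_seed, {
    tilt <- stats::rnorm(1, 0, config$jitter_angle_sd_deg)
    dx <- stats::rnorm(1, 0, config$jitter_lateral_sd_mm)
    lapply(seq_len(n), function(i) {
      m <- diag(4)
      m[1:3, 1:3] <- base_probe_rotation()
      m[1:3, 4] <- c(dx, y_probe, zf[i])
      pose_ct <- rigid_transform(m)
      if (tilt != 0) {
        # left-right rocking about the caudo-cranial travel axis through the
        # probe face, so the beam fans laterally at depth
        pose_ct <- compose(rt_rotation(tilt, c(0, 0, 1), pivot = m[1:3, 4]), pose_ct)
      }
      if (config$frame_noise_mm > 0 || config$frame_noise_deg > 0) {
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        pose_ct <- perturb_transform(pose_ct,
                                     angle_deg = stats::rnorm(1, 0, config$frame_noise_deg),
                                     axis = ax,
                                     translation_mm = stats::rnorm(3, 0, config$frame_noise_mm),
                                     pivot = m[1:3, 4])
      }
      compose(ct_to_ref, pose_ct)
    })
  })
}

# image-plane coordinates (mm) of the pixel grid; rows vary fastest
frame_pixel_coords <- function(config) {
  nr <- config$image_rows; nc <- config$n_cols; ps <- config$pixel_spacing_mm
  u <- (seq_len(nc) - (nc + 1) / 2) * ps
  v <- (seq_len(nr) - 1) * ps
  cbind(rep(u, each = nr), rep(v, times = nc), 0)
}

#' Simulate one ultrasound frame
#'
#' Casts each image column along the depth axis; at the first bone-labelled
#' voxel a Gaussian-profile echo is placed (narrower at higher frequency,
#' attenuated with depth), deeper pixels are shadowed, and the pre-surface
#' region is filled with low-amplitude speckle drawn from the current RNG
#' state (callers manage the speckle stream; [simulate_sweep()] seeds it
#' from the config). Values are clipped to [0, 1].
#'
#' @param pose frame pose (image -> reference).
#' @param phantom a `spine_phantom`.
#' @param config a [sweep_config()].
#' @param ref_to_ct true reference-to-CT transform.
#' @return a `tracked_frame`: list with `image` (rows x cols matrix) and
#'   `pose`.
#' @export
simulate_frame <- function(pose, phantom, config, ref_to_ct = rt_identity()) {
  nr <- config$image_rows; nc <- config$n_cols; ps <- config$pixel_spacing_mm
  img_to_ct <- compose(ref_to_ct, pose)
  pts <- apply_transform(img_to_ct, frame_pixel_coords(config))
  labs <- matrix(vol_value_at(phantom$labelmap, pts, outside = 0), nr, nc)
  img <- matrix(stats::runif(nr * nc, 0, config$speckle_ceiling), nr, nc)
  bone <- labs > 0
  hit_cols <- which(colSums(bone) > 0)
  if (length(hit_cols) > 0) {
    sigma_px <- config$echo_sigma_mm / ps
    rows <- seq_len(nr)
    for (cc in hit_cols) {
      r0 <- which(bone[, cc])[1]
      depth_mm <- (r0 - 1) * ps
      amp <- config$echo_amplitude *
        exp(-config$attenuation_per_mm_mhz * config$frequency_mhz * depth_mm)
      shadow <- rows > r0
      img[shadow, cc] <- img[shadow, cc] * 0.05
      img[, cc] <- img[, cc] + amp * exp(-(rows - r0)^2 / (2 * sigma_px^2))
    }
  }
  img[img > 1] <- 1
  img[img < 0] <- 0
  structure(list(image = img, pose = pose), class = "tracked_frame")
}

#' Simulate a full tracked sweep
#'
#' Plans the poses for the level (pose stream), then simulates each frame
#' with speckle drawn from the speckle stream. Deterministic per config
#' seed.
#'
#' @inheritParams plan_sweep_poses
#' @return a `tracked_sweep`: list with `frames`, `config`, `level`.
#' @export
simulate_sweep <- function(phantom, level, config, ref_to_ct = rt_identity()) {
  poses <- plan_sweep_poses(phantom, level, config, ref_to_ct)
  frames <- with_seed(config$speckle_seed, {
    lapply(poses, simulate_frame, phantom = phantom, config = config,
           ref_to_ct = ref_to_ct)
  })
  structure(list(frames = frames, config = config, level = as.integer(level)),
            class = "tracked_sweep")
}

#' @export
print.tracked_sweep <- function(x, ...) {
  cat(sprintf("<tracked_sweep> level %d, %d frames (%d x %d px), depth %g cm, %g MHz\n",
              x$level, length(x$frames), x$config$image_rows, x$config$n_cols,
              x$config$depth_cm, x$config$frequency_mhz))
  invisible(x)
}

#' Write a sweep to a directory (poses CSV + sidecar; frames as NIfTI stack)
#'
#' `poses.csv` holds one row per frame: `frame_index` plus the 16 row-major
#' pose entries. `meta.txt` records depth, frequency and seeds. The frame
#' stack is written as NIfTI when RNifti is available.
#'
#' @param sweep a `tracked_sweep`.
#' @param dir output directory (created if needed).
#' @export
write_sweep <- function(sweep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  poses <- t(vapply(sweep$frames, function(f) as.numeric(t(unclass(f$pose))), numeric(16)))
  df <- data.frame(frame_index = seq_len(nrow(poses)) - 1L, poses)
  names(df)[-1] <- paste0("m", rep(0:3, each = 4), rep(0:3, times = 4))
  utils::write.csv(df, file.path(dir, "poses.csv"), row.names = FALSE)
  writeLines(c(sprintf("depth_cm: %g", sweep$config$depth_cm),
               sprintf("frequency_mhz: %g", sweep$config$frequency_mhz),
               sprintf("n_frames: %d", length(sweep$frames)),
               sprintf("seed: %d", sweep$config$seed),
               sprintf("level: %d", sweep$level)),
             file.path(dir, "meta.txt"))
  if (requireNamespace("RNifti", quietly = TRUE)) {
    stack <- array(0, dim = c(dim(sweep$frames[[1]]$image), length(sweep$frames)))
    for (i in seq_along(sweep$frames)) stack[, , i] <- sweep$frames[[i]]$image
    RNifti::writeNifti(RNifti::asNifti(stack), file.path(dir, "frames.nii.gz"))
  }
  invisible(dir)
}
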