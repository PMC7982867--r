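test_that("phantom generation is deterministic and carries the study layout", {
  ph <- tiny_phantom()
  ph2 <- generate_phantom(tiny_phantom_config())
  expect_identical(ph$labelmap$data, ph2$labelmap$data)
  expect_identical(ph$ct$data, ph2$ct$data)

  full <- default_phantom()
  expect_equal(full$config$n_levels, 6)
  expect_equal(nrow(full$fiducials), 4)
  # fiducial spheres render bright in CT around each configured centre
  for (f in seq_len(4)) {
    v <- vol_value_at(full$ct, full$fiducials[f, , drop = FALSE])
    expect_gt(v, full$config$hu_bone * 2)
  }
  # all 5 region codes present for every level
  codes <- unique(as.integer(full$labelmap$data))
  for (lv in 1:6) expect_setequal(codes[codes %/% 10 == lv] %% 10, 1:5)
})

test_that("spinous apices are separated by the configured inter-level gaps", {
  full <- default_phantom()
  apex <- t(vapply(full$landmarks, function(m) m["spinous_apex", ], numeric(3)))
  gap_total <- sum(full$config$inter_level_distances_mm)
  expect_lt(abs((apex[1, 3] - apex[6, 3]) - gap_total),
            full$config$base_spacing_mm)
})

test_that("every landmark lies on a labelled voxel of its own level", {
  for (ph in list(tiny_phantom(), default_phantom())) {
    for (lv in seq_len(ph$config$n_levels)) {
      lm <- ph$landmarks[[lv]]
      expect_equal(nrow(lm), 7)
      codes <- vol_value_at(ph$labelmap, lm)
      expect_true(all(codes %/% 10 == lv))
    }
  }
})

test_that("overlapping vertebra primitives are rejected at config time", {
  cfg <- tiny_phantom_config()
  cfg$inter_level_distances_mm <- 10
  expect_error(generate_phantom(cfg), "overlap")
})

test_that("CT resampling preserves extent, identity and constant volumes", {
  ph <- tiny_phantom()
  same <- resample_ct(ph, ph$config$base_spacing_mm)
  expect_identical(same$data, ph$ct$data)
  half <- resample_ct(ph, 2)
  expect_true(all(abs(dim(half$data) - dim(ph$ct$data) / 2) <= 1))
  expect_error(resample_ct(ph, -1), "positive")
  expect_error(resample_ct(ph, 0.1), "base spacing")
  const <- volume3d(array(3.5, c(8, 8, 8)), spacing = 1)
  expect_true(all(abs(vol_resample(const, 1.7)$data - 3.5) < 1e-12))
})

test_that("sweep poses progress caudo-cranially with reproducible jitter", {
  ph <- tiny_phantom()
  cfg0 <- sweep_config(n_frames = 10, jitter_angle_sd_deg = 0,
                       jitter_lateral_sd_mm = 0, frame_noise_mm = 0,
                       frame_noise_deg = 0, seed = 3)
  poses <- plan_sweep_poses(ph, 1, cfg0)
  origins <- t(vapply(poses, function(p) unclass(p)[1:3, 4], numeric(3)))
  expect_true(all(diff(origins[, 3]) > 0))
  xaxes <- t(vapply(poses, function(p) unclass(p)[1:3, 1], numeric(3)))
  expect_lt(max(abs(sweep(xaxes, 2, xaxes[1, ]))), 1e-12)

  single <- plan_sweep_poses(ph, 1, sweep_config(n_frames = 1, seed = 3,
                                                 jitter_angle_sd_deg = 0,
                                                 jitter_lateral_sd_mm = 0,
                                                 frame_noise_mm = 0,
                                                 frame_noise_deg = 0))
  expect_equal(unclass(single[[1]])[3, 4], ph$level_centers_z[1])

  again <- plan_sweep_poses(ph, 1, cfg0)
  expect_identical(lapply(poses, unclass), lapply(again, unclass))
  expect_error(plan_sweep_poses(ph, 99, cfg0), "out of range")
})

test_that("seed splitting separates pose jitter from speckle texture", {
  ph <- tiny_phantom()
  a <- simulate_sweep(ph, 1, sweep_config(seed = 5, n_frames = 4))
  b <- simulate_sweep(ph, 1, sweep_config(seed = 5, n_frames = 4))
  expect_identical(a$frames[[2]]$image, b$frames[[2]]$image)
  # same pose stream, different speckle stream
  c <- simulate_sweep(ph, 1, sweep_config(seed = 5, speckle_seed = 999L,
                                          n_frames = 4))
  expect_identical(unclass(a$frames[[3]]$pose), unclass(c$frames[[3]]$pose))
  expect_false(identical(a$frames[[3]]$image, c$frames[[3]]$image))
})

test_that("frame simulation places the echo at the bone surface depth", {
  # flat slab orthogonal to the beam at a known physical depth
  lab <- slab_labelmap(code = 12L, dims = c(40, 60, 40), j_slab = 20L)
  ph <- list(labelmap = lab)
  cfg <- sweep_config(depth_cm = 5, frequency_mhz = 6, seed = 1)
  pose <- probe_pose_at(20, 55, 20)
  set.seed(2)
  fr <- simulate_frame(pose, ph, cfg)
  expect_true(all(fr$image >= 0 & fr$image <= 1))
  true_depth <- 55 - 19   # probe face to the slab voxel centre plane
  for (cc in seq_len(ncol(fr$image))) {
    r0 <- which.max(fr$image[, cc])
    expect_lt(abs((r0 - 1) * cfg$pixel_spacing_mm - true_depth),
              0.5 + 2 * cfg$pixel_spacing_mm)
  }
})

test_that("no-bone frames stay below the speckle ceiling", {
  lab <- volume3d(array(0L, c(20, 20, 20)), spacing = 1)
  cfg <- sweep_config(seed = 4)
  set.seed(8)
  fr <- simulate_frame(probe_pose_at(10, 18, 10), list(labelmap = lab), cfg)
  expect_lte(max(fr$image), cfg$speckle_ceiling)
})

test_that("echo width shrinks at the higher frequency", {
  lab <- slab_labelmap(code = 12L, dims = c(40, 60, 40), j_slab = 20L)
  ph <- list(labelmap = lab)
  pose <- probe_pose_at(20, 55, 20)
  fwhm <- function(freq) {
    cfg <- sweep_config(depth_cm = 5, frequency_mhz = freq, seed = 1)
    set.seed(3)
    fr <- simulate_frame(pose, ph, cfg)
    col <- fr$image[, 5]
    half <- max(col) / 2
    sum(col > half) * cfg$pixel_spacing_mm
  }
  expect_lt(fwhm(12), fwhm(6))
})

test_that("the full study grid enumerates 120 acquisitions", {
  cfg <- experiment_config()
  grid <- acquisition_grid(cfg)
  expect_equal(nrow(grid), 120)
  expect_equal(nrow(unique(grid[, c("level", "depth_cm", "frequency_mhz",
                                    "repetition")])), 120)
  expect_equal(anyDuplicated(grid$seed), 0)
  sweeps_per_level <- table(grid$level)
  expect_true(all(sweeps_per_level == 20))
})

test_that("sweep simulation is deterministic and sized by config", {
  ph <- tiny_phantom()
  cfg <- sweep_config(seed = 12, n_frames = 6)
  sw <- simulate_sweep(ph, 2, cfg)
  expect_equal(length(sw$frames), 6)
  expect_equal(dim(sw$frames[[1]]$image), c(cfg$image_rows, cfg$n_cols))
  sw2 <- simulate_sweep(ph, 2, cfg)
  expect_identical(lapply(sw$frames, `[[`, "image"),
                   lapply(sw2$frames, `[[`, "image"))
})

test_that("sweep config enforces the study grid and jitter signs", {
  expect_error(sweep_config(depth_cm = 6), "depth")
  expect_error(sweep_config(frequency_mhz = 9), "frequency")
  expect_error(sweep_config(jitter_angle_sd_deg = -1), "non-negative")
})
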