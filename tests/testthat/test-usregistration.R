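make_echo_frame <- function(nr = 60, nc = 5, echo_col = 3, echo_row = 20.3,
                            sigma = 2, amp = 0.9, pose = rt_identity()) {
  img <- matrix(0, nr, nc)
  img[, echo_col] <- amp * exp(-(seq_len(nr) - echo_row)^2 / (2 * sigma^2))
  structure(list(image = img, pose = pose), class = "tracked_frame")
}

test_that("bone-point extraction finds sub-pixel echoes and honours the shadow rule", {
  ps <- 0.4
  fr <- make_echo_frame()
  pts <- extract_bone_points_frame(fr, 0.45, 0.5, pixel_spacing_mm = ps)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$column, 3)
  expect_lt(abs(pts$row - 20.3), 0.5)
  expect_equal(pts$v_mm, (pts$row - 1) * ps)

  # speckle-only frame with the threshold above the speckle ceiling
  set.seed(1)
  sp_fr <- structure(list(image = matrix(runif(300, 0, 0.18), 60, 5),
                          pose = rt_identity()), class = "tracked_frame")
  expect_equal(nrow(extract_bone_points_frame(sp_fr, 0.45, 0.5,
                                              pixel_spacing_mm = ps)), 0)

  # a bright region deeper than the echo violates shadow confirmation
  bright <- make_echo_frame()
  bright$image[30:60, 3] <- 0.8
  expect_equal(nrow(extract_bone_points_frame(bright, 0.45, 0.5,
                                              pixel_spacing_mm = ps)), 0)

  expect_error(extract_bone_points_frame(fr, 1.5, 0.5, pixel_spacing_mm = ps),
               "thresholds")
})

test_that("clouds map frame points through the poses with provenance", {
  lab0 <- volume3d(array(0L, c(20, 20, 20)), spacing = 1)
  cfg <- sweep_config(seed = 2, n_frames = 3)
  sw <- simulate_sweep(list(labelmap = lab0, level_centers_z = 10,
                            config = list(n_levels = 1,
                                          vertebra_shape = list(sp = list(y_max = 16)))) |>
                         structure(class = "spine_phantom"),
                       1, cfg)
  cl <- sweep_to_cloud(sw)
  expect_true(cl$flagged_empty)
  expect_equal(nrow(cl$points), 0)

  pose <- random_rigid(5, max_angle_deg = 20, max_trans_mm = 10)
  fr <- make_echo_frame(pose = pose)
  sw1 <- make_test_sweep(list(pose), n_cols = 5, pixel_spacing_mm = 0.4,
                         images = list(fr$image))
  sw1$config <- sweep_config(seed = 1)
  sw1$config$n_cols <- 5L; sw1$config$pixel_spacing_mm <- 0.4
  sw1$frames <- list(fr)
  cl1 <- sweep_to_cloud(sw1)
  expect_equal(nrow(cl1$points), 1)
  bp <- extract_bone_points_frame(fr, pixel_spacing_mm = 0.4)
  expect_equal(as.numeric(cl1$points),
               as.numeric(apply_transform(pose, c(bp$u_mm, bp$v_mm, 0))))
  expect_equal(cl1$frame_index, 1L)
})

test_that("cloud points from a slab sweep land on the slab surface", {
  lab <- slab_labelmap(code = 12L, dims = c(40, 60, 40), j_slab = 20L)
  cfg <- sweep_config(depth_cm = 5, frequency_mhz = 6, seed = 6)
  poses <- lapply(seq(10, 30, length.out = 8), function(z) probe_pose_at(20, 55, z))
  set.seed(3)
  frames <- lapply(poses, simulate_frame, phantom = list(labelmap = lab), config = cfg)
  sw <- structure(list(frames = frames, config = cfg, level = 1L),
                  class = "tracked_sweep")
  cl <- sweep_to_cloud(sw)
  expect_gt(nrow(cl$points), 100)
  dist_to_surface <- abs(cl$points[, 2] - 19)
  expect_gte(mean(dist_to_surface <= 1), 0.95)
})

test_that("posterior surface extraction obeys first-hit occlusion", {
  slab <- slab_labelmap(code = 12L, dims = c(10, 30, 12), j_slab = 10L)
  s <- extract_ct_surface(slab, 1)
  expect_equal(nrow(s$points), 10 * 12)
  expect_true(all(s$points[, 2] == 9))

  two <- slab_labelmap(code = 12L, dims = c(10, 30, 12), j_slab = 10L)
  two$data[, 20, ] <- 12L           # second, more posterior slab
  s2 <- extract_ct_surface(two, 1)
  expect_true(all(s2$points[, 2] == 19))

  expect_error(extract_ct_surface(slab, 4), "absent")

  # phantom vertebra: no same-level labelled voxel posterior to any emitted point
  ph <- tiny_phantom()
  surf <- extract_ct_surface(ph$labelmap, 1)
  idx <- round(world_to_index(ph$labelmap, surf$points))
  lab <- ph$labelmap$data
  ny <- dim(lab)[2]
  ok <- vapply(seq_len(nrow(idx)), function(r) {
    js <- idx[r, 2]
    if (js == ny) return(TRUE)
    col <- lab[idx[r, 1], (js + 1):ny, idx[r, 3]]
    !any(col %/% 10 == 1)
  }, logical(1))
  expect_true(all(ok))
})

test_that("sweep-convention initialization is near-identity on identity scenes", {
  ph <- tiny_phantom()
  cfg <- sweep_config(seed = 9, jitter_angle_sd_deg = 0, jitter_lateral_sd_mm = 0,
                      frame_noise_mm = 0, frame_noise_deg = 0)
  sw <- simulate_sweep(ph, 1, cfg)
  init <- initialize_from_sweep(sw, ph, 1)
  ang <- acos(pmin(1, (sum(diag(unclass(init)[1:3, 1:3])) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1)
  expect_lt(sqrt(sum(unclass(init)[1:3, 4]^2)), 2)

  # reversing the frame order flips the initialization 180 deg about the beam
  swr <- sw
  swr$frames <- rev(sw$frames)
  init_r <- initialize_from_sweep(swr, ph, 1)
  rel <- unclass(compose(invert(init), init_r))[1:3, 1:3]
  expect_equal(diag(rel), c(-1, 1, -1), tolerance = 0.15)

  sw1 <- sw
  sw1$frames <- sw$frames[1]
  expect_error(initialize_from_sweep(sw1, ph, 1), "2 frames")
})

test_that("ICP is a fixed point on exact subsamples and monotone in RMS", {
  ph <- tiny_phantom()
  surf <- extract_ct_surface(ph$labelmap, 1)
  sub <- surf$points[seq(1, nrow(surf$points), by = 3), ]
  reg <- icp_register(sub, surf, init = rt_identity())
  expect_lt(reg$final_rms_mm, 1e-6)
  expect_lt(max(abs(unclass(reg$transform) - diag(4))), 1e-6)
  expect_true(all(diff(reg$rms_trace) <= 1e-9))
  expect_error(icp_register(matrix(numeric(0), 0, 3), surf), "empty")
})

test_that("ICP recovers small known perturbations on the default phantom", {
  ph <- default_phantom()
  surf <- extract_ct_surface(ph$labelmap, 3, stride = 2L)
  sub <- surf$points[seq(1, nrow(surf$points), by = 5), ]
  for (s in 1:3) {
    set.seed(800 + s)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    tru <- perturb_transform(rt_identity(), angle_deg = runif(1, -5, 5), axis = ax,
                             translation_mm = runif(3, -sqrt(3), sqrt(3)),
                             pivot = colMeans(sub))
    cloud <- apply_transform(tru, sub)
    reg <- icp_register(cloud, surf, init = rt_identity(), max_iter = 60)
    delta <- compose(reg$transform, tru)   # should be identity
    ang <- acos(pmin(1, (sum(diag(unclass(delta)[1:3, 1:3])) - 1) / 2)) * 180 / pi
    expect_lt(ang, 0.1)
    expect_lt(sqrt(sum(unclass(delta)[1:3, 4]^2)), 0.1)
    expect_true(all(diff(reg$rms_trace) <= 1e-9))
  }
})

test_that("an init displaced by one vertebral spacing locks onto the neighbour", {
  ph <- tiny_phantom()
  gap <- ph$config$inter_level_distances_mm
  surf_n <- extract_ct_surface(ph$labelmap, 1, include_neighbors = TRUE)
  sub <- extract_ct_surface(ph$labelmap, 1)$points
  sub <- sub[seq(1, nrow(sub), by = 4), ]
  reg <- icp_register(sub, surf_n, init = rt_translation(c(0, 0, -gap)),
                      max_iter = 60)
  # converges onto level 2, i.e. a translation of about -gap along the spine
  expect_lt(abs(unclass(reg$transform)[3, 4] + gap), 3)
  tre <- compute_tre(reg$transform, rt_identity(), ph$landmarks[[1]])
  expect_gte(tre, 10)
  expect_equal(as.character(classify_alignment(tre)), "level_mismatch")
})

test_that("most simulated study registrations meet the 2 mm navigation threshold", {
  run <- study_run()
  res <- run$results[run$results$resolution_mm == 0.5, ]
  expect_equal(nrow(res), 120)
  expect_gte(mean(res$classification == "success", na.rm = TRUE), 0.60)
})
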