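test_that("single-ray scenes count the first labelled voxel only", {
  # one column ray hitting a 1-voxel slab labelled L
  lab <- slab_labelmap(code = 12L, dims = c(9, 20, 9), j_slab = 10L)
  sw <- make_test_sweep(list(probe_pose_at(4, 18, 4)), n_cols = 1L,
                        pixel_spacing_mm = 1, depth_cm = 2, level = 1L)
  cov <- compute_coverage(sw, lab, rt_identity(), 1)
  expect_equal(unname(cov$counts), c(0L, 1L, 0L, 0L, 0L, 0L, 0L))

  # empty sweep: all bins zero
  sw0 <- make_test_sweep(list(), level = 1L)
  expect_true(all(compute_coverage(sw0, lab, rt_identity(), 1)$counts == 0))

  # occlusion: a voxel strictly behind another labelled voxel is not counted
  lab2 <- slab_labelmap(code = 12L, dims = c(9, 20, 9), j_slab = 10L)
  lab2$data[, 5, ] <- 15L     # deeper VB slab, fully occluded
  cov2 <- compute_coverage(sw, lab2, rt_identity(), 1)
  expect_equal(unname(cov2$counts["VB"]), 0L)

  expect_error(compute_coverage(sw, lab, rt_identity(), 1, step_mm = 2), "step")
})

test_that("adjacent levels pool into Inf/Sup and far levels are not counted", {
  lab <- volume3d(array(0L, c(9, 20, 30)), spacing = 1)
  lab$data[4, 10, 5] <- 31L    # level 3 = inferior neighbour of level 2
  lab$data[4, 10, 15] <- 21L   # own level
  lab$data[4, 10, 25] <- 11L   # superior neighbour
  lab$data[6, 10, 2] <- 41L    # two levels away: terminates but uncounted
  poses <- lapply(c(4, 14, 24), function(z) probe_pose_at(3, 18, z))
  poses[[4]] <- probe_pose_at(5, 18, 1)
  sw <- make_test_sweep(poses, n_cols = 1L, pixel_spacing_mm = 1,
                        depth_cm = 2, level = 2L)
  cov <- compute_coverage(sw, lab, rt_identity(), 2)
  expect_equal(unname(cov$counts[c("SP", "Inf", "Sup")]), c(1L, 1L, 1L))
  expect_equal(sum(cov$counts), 3)
})

test_that("coverage equals the brute-force marching oracle on random scenes", {
  for (s in 1:12) {
    sc <- random_coverage_scene(7000 + s)
    a <- compute_coverage(sc$sweep, sc$labelmap, rt_identity(), 2L)
    b <- coverage_oracle(sc$sweep, sc$labelmap, rt_identity(), 2L)
    expect_equal(unname(a$counts), unname(b), info = paste("scene", s))
  }
})

test_that("coverage is deterministic and monotone in added frames", {
  ph <- tiny_phantom()
  cfg <- sweep_config(seed = 31, n_frames = 8)
  sw <- simulate_sweep(ph, 1, cfg)
  c1 <- compute_coverage(sw, ph$labelmap, rt_identity(), 1)
  c2 <- compute_coverage(sw, ph$labelmap, rt_identity(), 1)
  expect_identical(c1$counts, c2$counts)
  for (k in c(2, 5, 8)) {
    swk <- sw
    swk$frames <- sw$frames[seq_len(k)]
    ck <- compute_coverage(swk, ph$labelmap, rt_identity(), 1)
    expect_true(all(ck$counts <= c1$counts))
    if (k > 2) expect_true(all(ck$counts >= prev$counts))
    prev <- ck
  }
})

test_that("the accuracy design has 15 fixed-effect columns and drops mismatches", {
  sim <- simulate_coverage_design(seed = 2)
  d <- build_accuracy_design(sim$histograms, sim$results)
  terms <- setdiff(names(d), c("tre_mm", "level", "level_frequency", "level_depth"))
  expect_length(terms, 15)            # 5 mains + choose(5, 2) interactions
  expect_true(all(c("SP_L", "L_AP", "TP_VB") %in% terms))
  expect_equal(d$SP_L, d$SP * d$L)

  # mismatch-classified acquisitions are excluded
  res <- sim$results
  res$tre_mm[3] <- 67.17
  res$classification <- as.character(classify_alignment(res$tre_mm))
  d2 <- build_accuracy_design(sim$histograms, res)
  expect_equal(nrow(d2), 119)

  # an all-zero coverage row is retained
  h0 <- sim$histograms; h0[5, 1:7] <- 0
  d3 <- build_accuracy_design(h0, sim$results)
  expect_true(all(d3[5, terms] == 0))
})

test_that("the misalignment response follows the 10 mm rule and own-level sum", {
  res <- data.frame(tre_mm = c(1.4, 67.17, 9.99, 10),
                    level = 1:4, depth_cm = 5, frequency_mhz = 6)
  h <- data.frame(SP = c(2, 0, 1, 1), L = c(3, 0, 0, 0), AP = 0, TP = 0,
                  VB = 0, Inf. = 9, Sup = 9)
  names(h)[6] <- "Inf"
  mm <- build_misalignment_response(res, h)
  expect_equal(mm$response, c(0L, 1L, 0L, 1L))
  expect_equal(mm$covariate[1], 5)    # Inf/Sup excluded
  expect_equal(nlevels(mm$groups$level), 4)
})

test_that("the accuracy model recovers a planted laminae effect", {
  sim <- simulate_coverage_design(effect_l = -0.001, noise_sd = 0.3, seed = 11)
  fit <- fit_accuracy_model(build_accuracy_design(sim$histograms, sim$results))
  lrow <- fit$coefficients[fit$coefficients$term == "L", ]
  expect_lt(lrow$estimate, 0)
  expect_lt(abs(lrow$estimate - (-0.001)), 2 * lrow$se)

  # zero-variance response: all slopes zero, flagged degenerate
  sim0 <- sim
  sim0$results$tre_mm <- 1.5
  fit0 <- fit_accuracy_model(build_accuracy_design(sim0$histograms, sim0$results))
  expect_true(all(fit0$coefficients$estimate[-1] == 0))
  expect_true(fit0$singular)
})

test_that("the mismatch model flags separation and is location invariant", {
  # strongly separated synthetic data
  sep_cov <- c(rep(100, 30), rep(4000, 90))
  sep_resp <- c(rep(1L, 30), rep(0L, 90))
  fit_sep <- fit_mismatch_model(sep_resp, sep_cov)
  expect_true(fit_sep$separated)
  expect_false(fit_sep$converged)

  expect_error(fit_mismatch_model(rep(0L, 10), rnorm(10)), "positive")

  # shifting the covariate by a constant leaves the slope unchanged (glm path)
  mm <- simulate_mismatch_data(slope = 8e-4, intercept = -4, seed = 13)
  f1 <- fit_mismatch_model(mm$response, mm$covariate)
  f2 <- fit_mismatch_model(mm$response, mm$covariate + 500)
  s1 <- f1$coefficients$estimate[f1$coefficients$term == "coverage_sum"]
  s2 <- f2$coefficients$estimate[f2$coefficients$term == "coverage_sum"]
  expect_equal(s1, s2, tolerance = 1e-6)

  # mixed version runs on the study grid and reports the covariate row
  f3 <- fit_mismatch_model(mm$response, mm$covariate, mm$groups)
  expect_true("coverage_sum" %in% f3$coefficients$term)
  expect_true(all(f3$coefficients$p_value >= 0 & f3$coefficients$p_value <= 1))
})
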