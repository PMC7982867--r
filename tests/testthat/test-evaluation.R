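test_that("TRE follows the translation and rotation closed forms", {
  set.seed(21)
  lm <- matrix(runif(21, -30, 30), ncol = 3)
  t_gt <- random_rigid(22)
  expect_equal(compute_tre(t_gt, t_gt, lm), 0)
  # pure relative translation: TRE equals its norm for any landmarks
  t_est <- compose(rt_translation(c(3, 4, 0)), t_gt)
  expect_equal(compute_tre(t_est, t_gt, lm), 5.0, tolerance = 1e-12)
  for (s in 1:5) {
    set.seed(30 + s)
    tr <- runif(3, -20, 20)
    expect_equal(compute_tre(compose(rt_translation(tr), t_gt), t_gt, lm),
                 sqrt(sum(tr^2)), tolerance = 1e-9)
  }
  # pure rotation about an axis through the landmark: chord length 2 d sin(theta/2)
  single <- rbind(c(50, 0, 0))
  rot <- perturb_transform(rt_identity(), 10, c(0, 0, 1), pivot = c(0, 0, 0))
  expect_equal(compute_tre(rot, rt_identity(), single),
               2 * 50 * sin(5 * pi / 180), tolerance = 1e-9)
  expect_error(compute_tre(t_gt, t_gt, matrix(numeric(0), 0, 3)), "empty")
})

test_that("classification partitions TRE with the stated boundary conventions", {
  expect_equal(as.character(classify_alignment(1.5)), "success")
  expect_equal(as.character(classify_alignment(2.0)), "failure")   # strict <
  expect_equal(as.character(classify_alignment(9.999)), "failure")
  expect_equal(as.character(classify_alignment(10.0)), "level_mismatch")
  expect_equal(as.character(classify_alignment(67.17)), "level_mismatch")
  expect_error(classify_alignment(-0.1), "non-negative")
  # every value maps to exactly one class
  set.seed(5)
  v <- c(runif(200, 0, 30), 2, 10)
  cl <- classify_alignment(v)
  expect_false(anyNA(cl))
  expect_error(eval_config(5, 3), "<")
})

test_that("rate summaries reproduce the study's percentage arithmetic", {
  mk <- function(n_succ, n_fail, n_mis) {
    tre <- c(runif(n_succ, 0.5, 1.9), runif(n_fail, 2.5, 9), runif(n_mis, 20, 80))
    data.frame(tre_mm = tre, classification = as.character(classify_alignment(tre)))
  }
  set.seed(9)
  r <- summarize_rates(mk(84, 22, 14))
  expect_equal(r$n, 120)
  expect_equal(r$pct_success, 100 * 84 / 120)      # 70.00
  expect_equal(r$pct_mismatch, 100 * 14 / 120)     # 11.67 at 2 dp
  expect_equal(round(r$pct_mismatch, 2), 11.67)
  expect_equal(r$pct_success + r$pct_failure + r$pct_mismatch, 100)
  r2 <- summarize_rates(mk(79, 41, 0))
  expect_equal(round(r2$pct_success, 2), 65.83)
  allfail <- summarize_rates(mk(0, 10, 0))
  expect_equal(allfail$pct_success, 0)
  expect_error(summarize_rates(data.frame()), "empty")
  # stratified: percentages computed within stratum
  df <- rbind(data.frame(mk(3, 1, 0), level = 1), data.frame(mk(1, 3, 0), level = 2))
  rs <- summarize_rates(df, by = "level")
  expect_equal(rs$pct_success, c(75, 25))
})

test_that("propagation matrices aggregate by the median with lever-arm structure", {
  base <- expand.grid(acq_level = 1:3, measured_level = 1:3)
  one <- data.frame(base, tre_mm = 1.25)
  expect_true(all(propagation_matrix(one) == 1.25))
  zero <- data.frame(base, tre_mm = 0)
  expect_true(all(propagation_matrix(zero) == 0))
  expect_error(propagation_matrix(one[-1, ]), "missing")

  # a pure rotation about the acquisition level centroid inflates
  # off-diagonal cells relative to the diagonal of the same row
  pos <- c(0, 40, 80)
  rows <- list()
  for (i in 1:3) {
    t_est <- perturb_transform(rt_identity(), 2, c(1, 0, 0),
                               pivot = c(0, 0, pos[i]))
    for (j in 1:3) {
      rows[[length(rows) + 1]] <- data.frame(
        acq_level = i, measured_level = j,
        tre_mm = compute_tre(t_est, rt_identity(),
                             rbind(c(0, 0, pos[j]), c(2, 1, pos[j]))))
    }
  }
  pm <- propagation_matrix(do.call(rbind, rows))
  for (i in 1:3) {
    off <- pm[i, -i]
    expect_true(all(off > pm[i, i]))
  }
})

test_that("cumulative level distances reproduce the measured spine geometry", {
  gaps <- c(69.36, 35.33, 38.21, 39.38, 39.46)
  d <- cumulative_level_distances(gaps)
  expect_equal(d["L1", "L6"], 221.74)
  expect_equal(d["L6", "L1"], 221.74)
  expect_true(all(diag(d) == 0))
  expect_equal(d["L1", "L2"], 39.46)   # most cranial pair
  expect_equal(d["L5", "L6"], 69.36)   # most caudal pair
  expect_equal(cumulative_level_distances(12.5)[1, 2], 12.5)
  expect_error(cumulative_level_distances(c(10, -1)), "positive")
})

test_that("TRE-distance regression recovers exact and noisy linear relations", {
  gaps <- c(69.36, 35.33, 38.21, 39.38, 39.46)
  d <- cumulative_level_distances(gaps)
  exact <- 0.02 * d + 1.0
  fit <- fit_tre_vs_distance(exact, d)
  expect_equal(fit$slope, 0.02, tolerance = 1e-10)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-10)
  expect_lt(fit$residual_rms_mm, 1e-10)

  const <- d * 0 + 2
  expect_equal(fit_tre_vs_distance(const, d)$slope, 0, tolerance = 1e-12)
  expect_error(fit_tre_vs_distance(const, d * 0), "degenerate")

  # normal-equations oracle on noisy data
  set.seed(77)
  noisy <- 0.02 * d + 1.0 + matrix(rnorm(36, 0, 0.1), 6, 6)
  fit_n <- fit_tre_vs_distance(noisy, d)
  x <- as.numeric(d); y <- as.numeric(noisy)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit_n$intercept, beta[1], tolerance = 1e-9)
  expect_equal(fit_n$slope, beta[2], tolerance = 1e-9)
})

test_that("intensity profiles interpolate trilinearly along the segment", {
  const <- volume3d(array(7, c(10, 10, 10)), spacing = 1)
  pr <- intensity_profile(const, c(1, 1, 1), c(8, 8, 8), 25)
  expect_true(all(abs(pr$intensity - 7) < 1e-12))
  expect_true(all(diff(pr$position_mm) > 0))

  ramp <- volume3d(array(rep(0:9, times = 100), c(10, 10, 10)), spacing = 1)
  pr2 <- intensity_profile(ramp, c(0, 5, 5), c(9, 5, 5), 19)
  expect_equal(pr2$intensity, seq(0, 9, length.out = 19), tolerance = 1e-9)

  expect_error(intensity_profile(const, c(1, 1, 1), c(1, 1, 1)), "distinct")
  expect_error(intensity_profile(const, c(1, 1, 1), c(50, 1, 1)), "outside")
})

test_that("profile ensembles report per-position median and IQR", {
  const <- volume3d(array(2, c(8, 8, 8)), spacing = 1)
  p1 <- intensity_profile(const, c(1, 1, 1), c(6, 1, 1), 10)
  st1 <- profile_ensemble_stats(list(p1))
  expect_equal(st1$median, p1$intensity)
  expect_true(all(st1$iqr == 0))

  p2 <- p1; p2$intensity <- p1$intensity + 2
  st2 <- profile_ensemble_stats(list(p1, p2))
  expect_true(all(abs(st2$median - 3) < 1e-12))
  expect_true(all(abs(st2$iqr - 1) < 1e-12))   # type-7 quantiles of {2, 4}

  p3 <- intensity_profile(const, c(1, 1, 1), c(6, 1, 1), 5)
  expect_error(profile_ensemble_stats(list(p1, p3)), "mismatched")
})

test_that("ultrasound profile spread is widest near the bone interface", {
  ph <- tiny_phantom()
  lam_lm <- ph$landmarks[[1]]["lamina_left", ]
  profiles <- list()
  for (s in 1:12) {
    cfg <- sweep_config(depth_cm = 5, frequency_mhz = 6, seed = 4000 + s,
                        n_frames = 12)
    sw <- simulate_sweep(ph, 1, cfg)
    # reconstruct a thin image volume around the lamina line in CT space and
    # profile across the interface
    mid <- sw$frames[[6]]
    img_to_ct <- mid$pose
    # sample the frame image along the beam over the lamina column
    cc <- round((lam_lm[1] - unclass(img_to_ct)[1, 4]) / cfg$pixel_spacing_mm +
                  (cfg$n_cols + 1) / 2)
    cc <- min(max(cc, 1), cfg$n_cols)
    col <- mid$image[, cc]
    depths <- (seq_along(col) - 1) * cfg$pixel_spacing_mm
    keep <- depths >= 10 & depths <= 40
    profiles[[s]] <- structure(list(position_mm = seq_len(sum(keep)),
                                    intensity = col[keep]),
                               class = "intensity_profile")
  }
  n <- min(lengths(lapply(profiles, `[[`, "intensity")))
  profiles <- lapply(profiles, function(p) {
    structure(list(position_mm = seq_len(n), intensity = p$intensity[seq_len(n)]),
              class = "intensity_profile")
  })
  st <- profile_ensemble_stats(profiles)
  # the spread peaks near the bone interface: the max-IQR sample sits within
  # a few mm of the median-intensity peak, and well above the speckle spread
  px <- sweep_config(depth_cm = 5, frequency_mhz = 6)$pixel_spacing_mm
  expect_lt(abs(which.max(st$iqr) - which.max(st$median)) * px, 5)
  quiet <- st$median < quantile(st$median, 0.4)
  expect_gt(max(st$iqr), 2 * median(st$iqr[quiet]))
})
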