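#' Full replica-experiment configuration
#'
#' Encodes the study grid: 5 repetitions x 2 frequencies x 2 depths x 6
#' vertebrae = 120 sweeps, evaluated against CT volumes at 0.5 / 1 / 2 mm.
#'
#' @param phantom a [phantom_config()].
#' @param depths_cm,frequencies_mhz,repetitions,levels the acquisition grid.
#' @param ct_resolutions_mm CT resolutions to evaluate (>= base spacing).
#' @param evaluation an [eval_config()].
#' @param n_frames frames per sweep.
#' @param fiducial_threshold CT intensity threshold for sphere detection.
#' @param tracking_noise_mm isotropic noise on tracked sphere positions.
#' @param master_seed master seed; all per-acquisition randomness derives
#'   from it via [acquisition_seed()].
#' @export
experiment_config <- function(phantom = phantom_config(),
                              depths_cm = c(5, 7),
                              frequencies_mhz = c(6, 12),
                              repetitions = 5L,
                              levels = seq_len(phantom$n_levels),
                              ct_resolutions_mm = c(0.5, 1, 2),
                              evaluation = eval_config(),
                              n_frames = 24L,
                              fiducial_threshold = 2000,
                              tracking_noise_mm = 0.1,
                              master_seed = 1L) {
  stopifnot(repetitions >= 1, length(levels) >= 1,
            all(ct_resolutions_mm >= phantom$base_spacing_mm - 1e-12))
  structure(list(phantom = phantom, depths_cm = depths_cm,
                 frequencies_mhz = frequencies_mhz,
                 repetitions = as.integer(repetitions),
                 levels = as.integer(levels),
                 ct_resolutions_mm = ct_resolutions_mm,
                 evaluation = evaluation, n_frames = as.integer(n_frames),
                 fiducial_threshold = fiducial_threshold,
                 tracking_noise_mm = tracking_noise_mm,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Acquisition grid and per-acquisition seeds
#'
#' The grid is the cross of levels x depths x frequencies x repetitions;
#' each acquisition gets a deterministic seed
#' `(master * 1000003 + level * 2000 + depth_index * 500 + frequency_index
#' * 250 + repetition * 7) mod (2^31 - 1)`, a stable scheme that lets a
#' single acquisition be re-simulated in isolation.
#'
#' @param config an [experiment_config()].
#' @export
acquisition_grid <- function(config) {
  g <- expand.grid(repetition = seq_len(config$repetitions),
                   frequency_mhz = config$frequencies_mhz,
                   depth_cm = config$depths_cm,
                   level = config$levels,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("level", "depth_cm", "frequency_mhz", "repetition")]
  g$seed <- mapply(function(lv, d, f, r) {
    acquisition_seed(config$master_seed, lv,
                     match(d, config$depths_cm), match(f, config$frequencies_mhz), r)
  }, g$level, g$depth_cm, g$frequency_mhz, g$repetition)
  g$acq_id <- sprintf("L%d_d%g_f%g_r%d", g$level, g$depth_cm, g$frequency_mhz,
                      g$repetition)
  g
}

#' @rdname acquisition_grid
#' @param master,level,depth_index,frequency_index,repetition seed inputs.
#' @export
acquisition_seed <- function(master, level, depth_index, frequency_index,
                             repetition) {
  as.integer((as.numeric(master) * 1000003 + level * 2000 + depth_index * 500 +
                frequency_index * 250 + repetition * 7) %% 2147483647)
}

#' Run the full replica experiment
#'
#' Generates the phantom, establishes the fiducial ground-truth alignment,
#' simulates every sweep of the grid, registers each sweep to the CT
#' surface at every requested resolution, computes TRE at all levels,
#' coverage histograms (base-resolution labelmap), stratified rate tables,
#' propagation matrices with distance regression, and the two coverage
#' models. Deterministic for a given master seed. Per-acquisition errors
#' are recorded and the pipeline continues.
#'
#' @param config an [experiment_config()].
#' @param progress print progress to stderr.
#' @return an `experiment_report` (see fields in the implementation);
#'   write it to files with [write_report()].
#' @export
run_experiment <- function(config = experiment_config(), progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  say("generating phantom")
  phantom <- generate_phantom(config$phantom)

  # true tracker-to-CT relationship of the scene, derived from the master seed
  truth <- with_seed(config$master_seed * 2 + 11, {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    perturb_transform(rt_identity(),
                      angle_deg = stats::runif(1, 5, 20), axis = ax,
                      translation_mm = stats::runif(3, -40, 40),
                      pivot = colMeans(phantom$fiducials))
  })
  tracked <- apply_transform(invert(truth), phantom$fiducials)
  if (config$tracking_noise_mm > 0) {
    tracked <- tracked + with_seed(config$master_seed * 2 + 13,
      matrix(stats::rnorm(length(tracked), 0, config$tracking_noise_mm),
             nrow(tracked), 3))
  }
  detection <- detect_fiducials(phantom$ct, config$fiducial_threshold)
  gt <- ground_truth_transform(detection, tracked)
  t_gt <- gt$transform

  say("resampling CT / labelmaps")
  resolutions <- config$ct_resolutions_mm
  labelmaps <- lapply(resolutions, function(s) resample_labelmap(phantom, s))
  names(labelmaps) <- as.character(resolutions)

  surfaces <- list()
  for (res in as.character(resolutions)) {
    for (lv in config$levels) {
      surfaces[[paste(res, lv)]] <-
        extract_ct_surface(labelmaps[[res]], lv, include_neighbors = TRUE,
                           stride = if (as.numeric(res) < 0.75) 2L else 1L)
    }
  }

  # landmarks expressed in the reference space via the ground truth, so that
  # TRE compares the estimated and ground-truth maps of the same points
  lm_ref <- lapply(phantom$landmarks, function(m) apply_transform(invert(t_gt), m))

  grid <- acquisition_grid(config)
  n_acq <- nrow(grid)
  long <- list(); own <- list(); cov_rows <- list()
  for (a in seq_len(n_acq)) {
    row <- grid[a, ]
    say("acquisition %d/%d (%s)", a, n_acq, row$acq_id)
    rec <- tryCatch({
      scfg <- sweep_config(depth_cm = row$depth_cm,
                           frequency_mhz = row$frequency_mhz,
                           n_frames = config$n_frames, seed = row$seed)
      sweep <- simulate_sweep(phantom, row$level, scfg, ref_to_ct = truth)
      cloud <- sweep_to_cloud(sweep)
      if (cloud$flagged_empty) stop("empty bone cloud")
      init <- initialize_from_sweep(sweep, phantom, row$level, cloud = cloud)
      cov <- compute_coverage(sweep, phantom$labelmap, t_gt, row$level)
      regs <- lapply(as.character(resolutions), function(res) {
        icp_register(cloud, surfaces[[paste(res, row$level)]], init = init)
      })
      names(regs) <- as.character(resolutions)
      list(sweep_ok = TRUE, cov = cov, regs = regs)
    }, error = function(e) list(sweep_ok = FALSE, error = conditionMessage(e)))
    if (!rec$sweep_ok) {
      own[[length(own) + 1]] <- data.frame(
        row[rep(1L, length(resolutions)), , drop = FALSE],
        resolution_mm = resolutions, tre_mm = NA_real_,
        classification = NA_character_, converged = NA, error = rec$error,
        row.names = NULL)
      next
    }
    cov_rows[[a]] <- data.frame(row, t(rec$cov$counts), check.names = FALSE)
    for (res in as.character(resolutions)) {
      t_est <- rec$regs[[res]]$transform
      tre_all <- vapply(config$levels, function(ml) {
        compute_tre(t_est, t_gt, lm_ref[[ml]])
      }, numeric(1))
      long[[length(long) + 1]] <- data.frame(
        row[rep(1L, length(config$levels)), , drop = FALSE],
        resolution_mm = as.numeric(res),
        acq_level = row$level, measured_level = config$levels, tre_mm = tre_all,
        row.names = NULL)
      tre_own <- tre_all[match(row$level, config$levels)]
      own[[length(own) + 1]] <- data.frame(
        row, resolution_mm = as.numeric(res), tre_mm = tre_own,
        classification = as.character(classify_alignment(tre_own, config$evaluation)),
        converged = rec$regs[[res]]$converged, error = NA_character_)
    }
  }
  results <- do.call(rbind, own)
  results_long <- do.call(rbind, long)
  coverage <- do.call(rbind, cov_rows)

  say("summarising")
  ok <- !is.na(results$tre_mm)
  rates_resolution <- summarize_rates(results[ok, ], by = "resolution_mm")
  rates_depth_freq <- summarize_rates(results[ok, ], by = c("depth_cm", "frequency_mhz"))
  rates_level <- summarize_rates(results[ok, ], by = "level")

  dist_mat <- cumulative_level_distances(config$phantom$inter_level_distances_mm)
  dist_mat <- dist_mat[config$levels, config$levels, drop = FALSE]
  propagation <- list(); distance_fits <- list()
  if (length(config$levels) > 1) {
    for (res in as.character(resolutions)) {
      sub <- results_long[results_long$resolution_mm == as.numeric(res) &
                            !is.na(results_long$tre_mm), ]
      pm <- propagation_matrix(sub, levels = config$levels)
      propagation[[res]] <- pm
      distance_fits[[res]] <- fit_tre_vs_distance(pm, dist_mat)
    }
  }

  # coverage models on the finest-resolution outcomes
  base_res <- as.character(min(resolutions))
  res0 <- results[results$resolution_mm == as.numeric(base_res) & ok, ]
  model_accuracy <- model_mismatch <- NULL
  if (!is.null(coverage) && nrow(res0) == nrow(coverage)) {
    design <- tryCatch(build_accuracy_design(coverage, res0), error = function(e) NULL)
    if (!is.null(design) && stats::sd(design$tre_mm) > 0) {
      model_accuracy <- tryCatch(fit_accuracy_model(design), error = function(e) NULL)
    }
    mm <- build_misalignment_response(res0, coverage,
                                      config$evaluation$mismatch_threshold_mm)
    if (length(unique(mm$response)) == 2) {
      model_mismatch <- tryCatch(
        fit_mismatch_model(mm$response, mm$covariate, mm$groups),
        error = function(e) NULL)
    }
  }

  structure(list(config = config, phantom = phantom,
                 ground_truth = list(transform = t_gt, fre_mm = gt$fre_mm,
                                     true_transform = truth),
                 grid = grid, results = results, results_long = results_long,
                 coverage = coverage,
                 rates_resolution = rates_resolution,
                 rates_depth_freq = rates_depth_freq,
                 rates_level = rates_level,
                 propagation = propagation, distance_fits = distance_fits,
                 model_accuracy = model_accuracy, model_mismatch = model_mismatch),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d acquisitions x %d resolutions\n",
              nrow(x$grid), length(x$config$ct_resolutions_mm)))
  print(x$rates_resolution, digits = 4)
  invisible(x)
}

#' Write an experiment report to CSV / text files
#'
#' Writes per-acquisition results, the long acquisition x measured-level
#' table, coverage histograms, stratified summaries (resolution rows then
#' depth x frequency rows, Table-1 layout), propagation matrices, model
#' coefficient tables, the ground-truth transform, and a provenance block.
#' Empty components give header-only CSVs.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (is.null(df)) df <- data.frame()
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  w(report$results, "results.csv")
  w(report$results_long, "results_long.csv")
  w(report$coverage, "coverage.csv")
  tab1_cols <- c("n", "median_tre_mm", "iqr_tre_mm", "pct_success")
  summary_tab <- rbind(
    if (NROW(report$rates_resolution)) {
      data.frame(stratum = paste0(report$rates_resolution$resolution_mm, " mm"),
                 report$rates_resolution[, tab1_cols])
    },
    if (NROW(report$rates_depth_freq)) {
      data.frame(stratum = sprintf("%g cm / %g MHz",
                                   report$rates_depth_freq$depth_cm,
                                   report$rates_depth_freq$frequency_mhz),
                 report$rates_depth_freq[, tab1_cols])
    })
  w(summary_tab, "summary.csv")
  w(report$rates_level, "rates_level.csv")
  for (res in names(report$propagation)) {
    utils::write.csv(report$propagation[[res]],
                     file.path(dir, sprintf("propagation_%smm.csv", res)))
  }
  if (!is.null(report$model_accuracy)) {
    w(report$model_accuracy$coefficients, "model_accuracy.csv")
  }
  if (!is.null(report$model_mismatch)) {
    w(report$model_mismatch$coefficients, "model_mismatch.csv")
  }
  if (!is.null(report$ground_truth)) {
    write_transform(report$ground_truth$transform, file.path(dir, "ground_truth.txt"))
  }
  writeLines(c(sprintf("package_version: %s",
                       as.character(utils::packageVersion("spinenav"))),
               sprintf("master_seed: %d", report$config$master_seed),
               sprintf("n_acquisitions: %d", NROW(report$grid)),
               sprintf("ct_resolutions_mm: %s",
                       paste(report$config$ct_resolutions_mm, collapse = " ")),
               sprintf("ground_truth_fre_mm: %.6f",
                       if (is.null(report$ground_truth)) NA_real_
                       else report$ground_truth$fre_mm),
               sprintf("complete: %s",
                       NROW(report$results) > 0 && !anyNA(report$results$tre_mm))),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}

#' Simulate a coverage design with a planted label effect
#'
#' Draws coverage counts emulating the study's histogram scale (AP highest,
#' then L and SP; TP and VB visible only at 7 cm depth) over the full
#' 6 x 2 x 2 x 5 grid, and a TRE response
#' `tre = intercept + effect_l * L + noise` with independent Gaussian
#' noise; used to validate that the accuracy model recovers a planted
#' laminae-coverage effect and controls its type-I error.
#'
#' @param effect_l planted laminae coefficient (mm per voxel; 0 for null).
#' @param intercept baseline TRE (mm).
#' @param noise_sd residual SD (mm).
#' @param seed RNG seed.
#' @return list with `histograms`, `results` (ready for
#'   [build_accuracy_design()]).
#' @export
simulate_coverage_design <- function(effect_l = -0.001, intercept = 1.5,
                                     noise_sd = 0.3, seed = 1L) {
  grid <- expand.grid(repetition = 1:5, frequency_mhz = c(6, 12),
                      depth_cm = c(5, 7), level = 1:6, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  with_seed(seed, {
    deep <- grid$depth_cm == 7
    h <- data.frame(
      SP = round(pmax(0, stats::rnorm(n, 944, 200))),
      L = round(pmax(0, stats::rnorm(n, 1004, 250))),
      AP = round(pmax(0, stats::rnorm(n, 1486, 300))),
      TP = ifelse(deep, round(pmax(0, stats::rnorm(n, 150, 60))), 0),
      VB = ifelse(deep, round(pmax(0, stats::rnorm(n, 40, 20))), 0),
      Inf. = round(pmax(0, stats::rnorm(n, 2000, 400))),
      Sup = round(pmax(0, stats::rnorm(n, 2000, 400))))
    names(h)[6] <- "Inf"
    tre <- intercept + effect_l * h$L + stats::rnorm(n, 0, noise_sd)
    tre <- pmax(tre, 0.05)
    results <- data.frame(grid,
                          tre_mm = tre,
                          classification = classify_alignment(tre))
    list(histograms = h, results = results)
  })
}

#' Simulate binary mismatch outcomes over the study grid
#'
#' Bernoulli responses with `logit p = intercept + slope * coverage_sum`;
#' used for the null calibration of the misalignment model.
#'
#' @param slope logistic slope on the own-level coverage sum (0 for null).
#' @param intercept logistic intercept.
#' @param seed RNG seed.
#' @return list with `response`, `covariate`, `groups`.
#' @export
simulate_mismatch_data <- function(slope = 0, intercept = -2, seed = 1L) {
  grid <- expand.grid(repetition = 1:5, frequency_mhz = c(6, 12),
                      depth_cm = c(5, 7), level = 1:6, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  with_seed(seed, {
    covariate <- round(pmax(0, stats::rnorm(n, 3500, 700)))
    p <- stats::plogis(intercept + slope * covariate)
    response <- stats::rbinom(n, 1, p)
    groups <- data.frame(
      level = factor(grid$level),
      level_frequency = factor(paste(grid$level, grid$frequency_mhz, sep = ":")),
      level_depth = factor(paste(grid$level, grid$depth_cm, sep = ":")))
    list(response = response, covariate = covariate, groups = groups)
  })
}
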